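# C-HORSE: a rate-coded, inhibition-constrained autoencoder of the
# hippocampus with a trisynaptic pathway (EC_in -> DG -> CA3 -> CA1; sparse
# connectivity, high inhibition) and a monosynaptic pathway (EC_in -> CA1;
# full connectivity, low inhibition), trained with Contrastive Hebbian
# Learning to reproduce 26-unit satellite patterns on EC_out.

#' Encode a satellite set as 26-unit binary training patterns
#'
#' One unit per satellite feature: per category 1 class unit, 4 codename
#' units, and 8 part units, the two categories occupying disjoint unit
#' subsets. Each satellite pattern has exactly 6 active units (class +
#' codename + its 4 parts).
#'
#' @param set Trained `satellite_set`.
#' @return List of class `pattern_set`: `patterns` (8 x 26 binary matrix,
#'   rows named by satellite), `units` (tibble: `unit`, `category`,
#'   `unit_type`, `label`, `part_type`, `role`).
#' @export
build_patterns <- function(set) {
  stopifnot(inherits(set, "satellite_set"), !any(set$novel))
  units <- list()
  for (cat_name in CATEGORIES) {
    cs <- set %>% filter(.data$category == cat_name)
    sats <- unique(cs$satellite_id)
    parts <- part_table(cs) %>% arrange(.data$role, .data$part_type)
    units[[length(units) + 1L]] <- tibble(
      category = cat_name,
      unit_type = c("class", rep("code", length(sats)), rep("part", nrow(parts))),
      label = c(cat_name, sats, parts$part_id),
      part_type = c(NA_character_, rep(NA_character_, length(sats)), parts$part_type),
      role = c(NA_character_, rep(NA_character_, length(sats)), parts$role)
    )
  }
  units <- bind_rows(units) %>% mutate(unit = row_number()) %>%
    select("unit", dplyr::everything())
  sats <- unique(set$satellite_id)
  pat <- matrix(0, nrow = length(sats), ncol = nrow(units),
                dimnames = list(sats, NULL))
  for (s in sats) {
    cs <- set %>% filter(.data$satellite_id == s)
    cat_name <- cs$category[1]
    on <- c(which(units$unit_type == "class" & units$category == cat_name),
            which(units$unit_type == "code" & units$label == s),
            which(units$unit_type == "part" & units$label %in% cs$part_id))
    pat[s, on] <- 1
  }
  structure(list(patterns = pat, units = units), class = "pattern_set")
}

#' Network hyperparameters
#'
#' Defaults give the canonical architecture: hidden layers DG 400, CA3 80,
#' CA1 100 units; sparse trisynaptic projections (EC_in->DG 0.25,
#' EC_in->CA3 0.25, DG->CA3 0.05) with fixed fan-in sampling; k-winners-take-
#' all inhibition with active fractions DG `k_base / dg_gi` (4% at the default
#' conductance knob Gi = 6), CA3 12%, CA1 15%, so DG is the sparsest and CA1
#' the least sparse hidden layer; logistic unit transfer; soft-bounded
#' Contrastive Hebbian Learning with a conditional-PCA Hebbian mix on the
#' representation-forming projections. The defaults are the shipped,
#' calibrated operating point of the model.
#'
#' @param n_dg,n_ca3,n_ca1 Hidden layer sizes.
#' @param frac_ec_dg,frac_ec_ca3,frac_dg_ca3 Connectivity fractions of the
#'   sparse trisynaptic projections (proportion of senders contacting each
#'   receiver; fixed fan-in).
#' @param dg_gi DG inhibition conductance knob; the DG active fraction is
#'   `k_base / dg_gi` so higher Gi means sparser DG.
#' @param k_base Base sparsity constant mapping `dg_gi` to a k-fraction.
#' @param k_frac_ca3,k_frac_ca1 kWTA active fractions for CA3 and CA1.
#' @param k_frac_out kWTA active fraction of the unclamped EC_out layer
#'   (default 8/26, slightly above the 6 active units of a satellite pattern
#'   so marginal winners are not displaced by a single false alarm).
#' @param gain_hidden,theta_hidden Hidden-unit logistic gain and threshold
#'   floor (the kWTA threshold adapts upward from this floor).
#' @param gain_ca1 Logistic gain of the CA1 layer (defaults to
#'   `gain_hidden`); CA1's effective sharpness scales with the projection
#'   drive, so this compensates when `ca3_ca1_scale` is raised.
#' @param gain_ec,theta_ec,theta_out EC layer logistic gain and thresholds.
#' @param dt Integration step of the settling dynamics (per cycle).
#' @param loop_scale Strength of the one-to-one big-loop EC_out -> EC_in
#'   projection relative to external input.
#' @param ca3_ca1_scale Relative strength of the CA3 -> CA1 (trisynaptic)
#'   drive against the direct EC_in -> CA1 drive; values above 1 let the
#'   pattern-separated CA3 code tip CA1 winners toward item-specific units.
#' @param msp_ca1_scale Relative strength of the direct EC_in -> CA1
#'   (monosynaptic) drive; values below 1 keep the category-integrating MSP
#'   drive from swamping the item-specific CA3 code in the intact network.
#' @param n_cycles Settling cycles per phase (training and test).
#' @param lr_tsp,lr_msp,lr_out Learning rates for trisynaptic projections,
#'   EC_in->CA1, and CA1->EC_out.
#' @param k_hebb_msp,k_hebb_tsp Proportion of conditional-PCA Hebbian
#'   learning mixed into the error-driven CHL update on the monosynaptic
#'   (EC_in->CA1) and trisynaptic representation projections (the readout
#'   CA1->EC_out stays purely error-driven). 0 gives pure CHL.
#' @param w_init Range of the uniform weight initialization.
#' @param ec_act_frac Expected active fraction of EC layers (6 of 26 units),
#'   used to normalize projection drive.
#' @param score_all_units If `TRUE`, reconstruction accuracy scores all 26
#'   EC_out units against the pattern; default scores the pattern's active
#'   units only.
#' @return List of class `chorse_config`.
#' @export
network_config <- function(n_dg = 400L, n_ca3 = 80L, n_ca1 = 100L,
                           frac_ec_dg = 0.25, frac_ec_ca3 = 0.25,
                           frac_dg_ca3 = 0.05,
                           dg_gi = 6, k_base = 0.24,
                           k_frac_ca3 = 0.12, k_frac_ca1 = 0.15,
                           k_frac_out = 8 / 26,
                           gain_hidden = 10, theta_hidden = 0.5,
                           gain_ca1 = NULL,
                           gain_ec = 30, theta_ec = 0.5, theta_out = 0.3,
                           dt = 0.5, loop_scale = 0.5, ca3_ca1_scale = 2,
                           msp_ca1_scale = 1,
                           n_cycles = 100L,
                           lr_tsp = 0.1, lr_msp = 0.05, lr_out = 0.3,
                           k_hebb_msp = 0.4, k_hebb_tsp = 0.3,
                           w_init = c(0.25, 0.75),
                           ec_act_frac = 6 / 26,
                           score_all_units = FALSE) {
  fracs <- c(frac_ec_dg, frac_ec_ca3, frac_dg_ca3)
  if (any(fracs <= 0 | fracs > 1)) abort("connectivity fractions must lie in (0, 1]")
  if (dg_gi <= 0) abort("dg_gi must be positive")
  cfg <- as.list(environment())
  if (is.null(cfg$gain_ca1)) cfg$gain_ca1 <- gain_hidden
  cfg$k_dg <- max(1L, as.integer(round(n_dg * k_base / dg_gi)))
  cfg$k_ca3 <- max(1L, as.integer(round(n_ca3 * k_frac_ca3)))
  cfg$k_ca1 <- max(1L, as.integer(round(n_ca1 * k_frac_ca1)))
  cfg$k_out <- max(1L, as.integer(round(26 * k_frac_out)))
  structure(cfg, class = "chorse_config")
}

#' Lesion configuration
#'
#' @param msp Lesion the monosynaptic pathway (EC_in -> CA1 set to 0): the
#'   "TSP only" model.
#' @param tsp Lesion the trisynaptic pathway (EC_in -> DG, EC_in -> CA3,
#'   DG -> CA3, CA3 -> CA1 set to 0): the "MSP only" model.
#' @param bigloop Lesion the EC_out -> EC_in recurrence (used at test to read
#'   CA1's "initial response").
#' @return List of class `lesion_config`.
#' @export
lesion_config <- function(msp = FALSE, tsp = FALSE, bigloop = FALSE) {
  if (msp && tsp) abort("msp and tsp cannot both be lesioned")
  structure(list(msp = msp, tsp = tsp, bigloop = bigloop),
            class = "lesion_config")
}

# Condition label ("intact", "msp_only", "tsp_only") -> lesion_config.
condition_lesion <- function(condition) {
  switch(condition,
         intact = lesion_config(),
         msp_only = lesion_config(tsp = TRUE),
         tsp_only = lesion_config(msp = TRUE),
         abort(paste0("unknown condition: ", condition)))
}

fixed_fan_in_mask <- function(n_dst, n_src, frac) {
  fan_in <- max(1L, as.integer(round(frac * n_src)))
  M <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) M[i, sample.int(n_src, fan_in)] <- 1
  M
}

#' Initialize a network
#'
#' Samples sparse connectivity masks (fixed fan-in per receiver) and uniform
#' initial weights on existing connections; lesioned projections are zeroed
#' and frozen. Deterministic given the seed.
#'
#' @param config A `chorse_config`.
#' @param lesions A `lesion_config`.
#' @param seed Integer RNG seed.
#' @param n_ec Input/output dimensionality (26 for the satellite patterns).
#' @return List of class `chorse_network`: weight matrices `W`, masks `M`,
#'   `config`, `lesions`, `par` (settling parameters), `seed`.
#' @export
init_network <- function(config = network_config(), lesions = lesion_config(),
                         seed = 1L, n_ec = 26L) {
  stopifnot(inherits(config, "chorse_config"), inherits(lesions, "lesion_config"))
  with_seed(seed, {
    dims <- list(ec_dg = c(config$n_dg, n_ec),
                 ec_ca3 = c(config$n_ca3, n_ec),
                 dg_ca3 = c(config$n_ca3, config$n_dg),
                 ca3_ca1 = c(config$n_ca1, config$n_ca3),
                 ec_ca1 = c(config$n_ca1, n_ec),
                 ca1_out = c(n_ec, config$n_ca1))
    M <- list(ec_dg = fixed_fan_in_mask(config$n_dg, n_ec, config$frac_ec_dg),
              ec_ca3 = fixed_fan_in_mask(config$n_ca3, n_ec, config$frac_ec_ca3),
              dg_ca3 = fixed_fan_in_mask(config$n_ca3, config$n_dg, config$frac_dg_ca3),
              ca3_ca1 = matrix(1, config$n_ca1, config$n_ca3),
              ec_ca1 = matrix(1, config$n_ca1, n_ec),
              ca1_out = matrix(1, n_ec, config$n_ca1))
    W <- lapply(names(dims), function(nm) {
      d <- dims[[nm]]
      matrix(runif(prod(d), config$w_init[1], config$w_init[2]), d[1], d[2]) * M[[nm]]
    })
    names(W) <- names(dims)
    if (lesions$msp) {
      W$ec_ca1[] <- 0
      M$ec_ca1[] <- 0
    }
    if (lesions$tsp) {
      for (nm in c("ec_dg", "ec_ca3", "dg_ca3", "ca3_ca1")) {
        W[[nm]][] <- 0
        M[[nm]][] <- 0
      }
    }
    fan <- function(nm) max(1, round(switch(nm,
      ec_dg = config$frac_ec_dg * n_ec, ec_ca3 = config$frac_ec_ca3 * n_ec,
      dg_ca3 = config$frac_dg_ca3 * config$n_dg)))
    par <- list(
      s_ec_dg = 1 / (fan("ec_dg") * config$ec_act_frac),
      s_ec_ca3 = 1 / (fan("ec_ca3") * config$ec_act_frac),
      s_dg_ca3 = 1 / (fan("dg_ca3") * config$k_dg / config$n_dg),
      s_ca3_ca1 = config$ca3_ca1_scale / config$k_ca3,
      s_ec_ca1 = config$msp_ca1_scale / (n_ec * config$ec_act_frac),
      s_ca1_out = 1 / (config$n_ca1 * config$k_ca1 / config$n_ca1),
      k_dg = config$k_dg, k_ca3 = config$k_ca3, k_ca1 = config$k_ca1,
      k_out = config$k_out,
      gain_hidden = config$gain_hidden, gain_ca1 = config$gain_ca1,
      theta_hidden = config$theta_hidden,
      gain_ec = config$gain_ec, theta_ec = config$theta_ec,
      theta_out = config$theta_out, loop_scale = config$loop_scale,
      dt = config$dt)
    structure(list(W = W, M = M, config = config, lesions = lesions,
                   par = par, n_ec = n_ec, seed = seed),
              class = "chorse_network")
  })
}

#' Settle the network on an input pattern
#'
#' Clamps the Input layer, optionally clamps EC_out, and runs the rate
#' dynamics for `n_cycles` cycles. `pathway` silences the excluded pathway's
#' projections (used for the CHL minus phases); lesions always apply.
#'
#' @param net A `chorse_network`.
#' @param input Numeric vector of length `n_ec` in `[0, 1]`.
#' @param output_clamp Optional pattern clamped on EC_out.
#' @param pathway `"both"`, `"tsp_only"`, or `"msp_only"`.
#' @param n_cycles Number of settling cycles (> 0).
#' @param bigloop Allow EC_out -> EC_in recurrence (overridden to off by a
#'   big-loop lesion).
#' @return Named list of layer activation vectors (`ec_in`, `dg`, `ca3`,
#'   `ca1`, `ec_out`), each bounded in `[0, 1]`.
#' @export
settle <- function(net, input, output_clamp = NULL,
                   pathway = c("both", "tsp_only", "msp_only"),
                   n_cycles = NULL, bigloop = TRUE) {
  pathway <- match.arg(pathway)
  stopifnot(inherits(net, "chorse_network"), length(input) == net$n_ec)
  if (is.null(n_cycles)) n_cycles <- net$config$n_cycles
  if (n_cycles <= 0) abort("n_cycles must be positive")
  tsp_on <- pathway %in% c("both", "tsp_only") && !net$lesions$tsp
  msp_on <- pathway %in% c("both", "msp_only") && !net$lesions$msp
  loop_on <- bigloop && !net$lesions$bigloop
  out <- settle_cpp(net$W$ec_dg, net$W$ec_ca3, net$W$dg_ca3, net$W$ca3_ca1,
                    net$W$ec_ca1, net$W$ca1_out, as.numeric(input),
                    if (is.null(output_clamp)) NULL else as.numeric(output_clamp),
                    tsp_on, msp_on, loop_on, as.integer(n_cycles), net$par)
  lapply(out, as.vector)
}

# Soft-bounded CHL weight update with an optional CPCA Hebbian mix (the
# lineage's learning rule combines error-driven CHL with conditional-PCA
# Hebbian learning). Error term: dw = (pre+ post+ - pre- post-), positive
# deltas scaled by (1 - w), negative by w. Hebbian term: dw = post+ (pre+ - w),
# self-bounding on [0, 1]. Masked to existing connections.
chl_update <- function(W, M, pre_p, post_p, pre_m, post_m, lr, k_hebb = 0) {
  d <- lr * (1 - k_hebb) * (outer(post_p, pre_p) - outer(post_m, pre_m)) * M
  W <- W + pmax(d, 0) * (1 - W) + pmin(d, 0) * W
  if (k_hebb > 0) {
    h <- lr * k_hebb * (outer(post_p, rep(1, length(pre_p))) *
                          (outer(rep(1, length(post_p)), pre_p) - W)) * M
    W <- W + h
  }
  W
}

#' One Contrastive Hebbian Learning trial
#'
#' Runs the plus phase (input and output clamped, both surviving pathways)
#' and one minus phase per surviving pathway (input clamped, that pathway
#' alone). Each projection is updated from the minus phase in which it was
#' active; CA1 -> EC_out, active in every phase, splits its learning rate
#' across the minus phases run.
#'
#' @param net A `chorse_network`.
#' @param pattern 26-unit binary pattern.
#' @return Updated network; the phase activation snapshots are attached as
#'   `net$phases`.
#' @export
chl_trial <- function(net, pattern) {
  cfg <- net$config
  plus <- settle(net, pattern, output_clamp = pattern, pathway = "both")
  phases <- list(plus = plus)
  minus <- list()
  if (!net$lesions$tsp) minus$tsp <- settle(net, pattern, pathway = "tsp_only")
  if (!net$lesions$msp) minus$msp <- settle(net, pattern, pathway = "msp_only")
  phases <- c(phases, stats::setNames(minus, paste0("minus_", names(minus))))

  if (!is.null(minus$tsp)) {
    m <- minus$tsp
    net$W$ec_dg <- chl_update(net$W$ec_dg, net$M$ec_dg, plus$ec_in, plus$dg,
                              m$ec_in, m$dg, cfg$lr_tsp, cfg$k_hebb_tsp)
    net$W$ec_ca3 <- chl_update(net$W$ec_ca3, net$M$ec_ca3, plus$ec_in, plus$ca3,
                               m$ec_in, m$ca3, cfg$lr_tsp, cfg$k_hebb_tsp)
    net$W$dg_ca3 <- chl_update(net$W$dg_ca3, net$M$dg_ca3, plus$dg, plus$ca3,
                               m$dg, m$ca3, cfg$lr_tsp, cfg$k_hebb_tsp)
    net$W$ca3_ca1 <- chl_update(net$W$ca3_ca1, net$M$ca3_ca1, plus$ca3, plus$ca1,
                                m$ca3, m$ca1, cfg$lr_tsp, cfg$k_hebb_tsp)
  }
  if (!is.null(minus$msp)) {
    m <- minus$msp
    net$W$ec_ca1 <- chl_update(net$W$ec_ca1, net$M$ec_ca1, plus$ec_in, plus$ca1,
                               m$ec_in, m$ca1, cfg$lr_msp, cfg$k_hebb_msp)
  }
  lr_o <- cfg$lr_out / length(minus)
  for (m in minus) {
    net$W$ca1_out <- chl_update(net$W$ca1_out, net$M$ca1_out, plus$ca1,
                                plus$ec_out, m$ca1, m$ec_out, lr_o)
  }
  net$phases <- phases
  net
}

#' Score a reconstruction
#'
#' @param ec_out EC_out activation vector.
#' @param pattern Target binary pattern.
#' @param all_units Score all units on the correct side of 0.5 instead of
#'   only the pattern's active units.
#' @return Proportion correct in `[0, 1]`.
#' @export
reconstruction_score <- function(ec_out, pattern, all_units = FALSE) {
  if (all_units) mean((ec_out > 0.5) == (pattern > 0.5))
  else mean(ec_out[pattern > 0.5] > 0.5)
}

#' Reconstruction accuracy on full patterns
#'
#' Settles with the input clamped (no output clamp, surviving pathways,
#' big loop intact) and returns the mean proportion of each pattern's active
#' units whose EC_out activation exceeds 0.5.
#'
#' @param net A `chorse_network`.
#' @param patterns A `pattern_set` or a binary matrix (patterns in rows) or a
#'   single pattern vector.
#' @return Mean accuracy in `[0, 1]`.
#' @export
evaluate_reconstruction <- function(net, patterns) {
  if (inherits(patterns, "pattern_set")) patterns <- patterns$patterns
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  acc <- vapply(seq_len(nrow(patterns)), function(i) {
    out <- settle(net, patterns[i, ])$ec_out
    reconstruction_score(out, patterns[i, ], net$config$score_all_units)
  }, numeric(1))
  mean(acc)
}

#' Train a network on the satellite patterns
#'
#' Each epoch presents every pattern twice in seeded random order (16 trials
#' for the 8 satellites), applying one CHL trial per presentation. The network
#' is tested before training (epoch 0) and after every epoch.
#'
#' @param net A `chorse_network`.
#' @param patterns A `pattern_set` or binary pattern matrix.
#' @param n_epochs Number of training epochs (default 6).
#' @param seed Integer RNG seed for the trial orders.
#' @return The trained network with `net$log`, a tibble of per-epoch
#'   reconstruction accuracy (epoch 0 = untrained), and `net$trial_orders`.
#' @export
train_network <- function(net, patterns, n_epochs = 6L, seed = 1L) {
  if (inherits(patterns, "pattern_set")) patterns <- patterns$patterns
  log <- tibble(epoch = 0L, accuracy = evaluate_reconstruction(net, patterns))
  orders <- list()
  for (ep in seq_len(n_epochs)) {
    ord <- with_seed(seed + ep, sample(rep(seq_len(nrow(patterns)), 2L)))
    orders[[ep]] <- ord
    for (i in ord) net <- chl_trial(net, patterns[i, ])
    log <- bind_rows(log, tibble(epoch = as.integer(ep),
                                 accuracy = evaluate_reconstruction(net, patterns)))
  }
  net$log <- log
  net$trial_orders <- orders
  net
}

#' CA1 initial response to a single feature probe
#'
#' Settles on a one-hot probe with the big loop lesioned (CA1 cannot
#' influence DG and CA3) and returns the CA1 snapshot.
#'
#' @param net A `chorse_network`.
#' @param feature_unit Index of the probed unit (1-26).
#' @param n_cycles Settling cycles (default 100).
#' @return CA1 activation vector.
#' @export
probe_feature <- function(net, feature_unit, n_cycles = 100L) {
  stopifnot(feature_unit >= 1, feature_unit <= net$n_ec)
  probe <- numeric(net$n_ec)
  probe[feature_unit] <- 1
  settle(net, probe, n_cycles = n_cycles, bigloop = FALSE)$ca1
}

#' CA1 initial responses to every feature
#'
#' @param net A `chorse_network`.
#' @param n_cycles Settling cycles per probe.
#' @return Matrix (features x CA1 units).
#' @export
probe_features <- function(net, n_cycles = 100L) {
  t(vapply(seq_len(net$n_ec), function(u) probe_feature(net, u, n_cycles),
           numeric(net$config$n_ca1)))
}

#' Train a cohort of model initializations
#'
#' For each condition and seed: initialize (with the condition's lesions
#' present during training and testing), train for `n_epochs` epochs, record
#' the per-epoch accuracy log and the per-feature CA1 initial-response
#' matrix.
#'
#' @param patterns A `pattern_set`.
#' @param config A `chorse_config`.
#' @param conditions Subset of `c("intact", "msp_only", "tsp_only")`.
#' @param n_inits Initializations per condition (default 50).
#' @param master_seed Master seed; per-init seeds are derived from it.
#' @param n_epochs Training epochs.
#' @return List of class `chorse_cohort`: `accuracy` (tibble condition x
#'   init x epoch), `probes` (nested list of feature x CA1 matrices),
#'   `units`, `config`, `master_seed`.
#' @export
run_cohort <- function(patterns, config = network_config(),
                       conditions = c("intact", "msp_only", "tsp_only"),
                       n_inits = 50L, master_seed = 1L, n_epochs = 6L) {
  stopifnot(inherits(patterns, "pattern_set"))
  acc <- list()
  probes <- list()
  for (cond in conditions) {
    les <- condition_lesion(cond)
    probes[[cond]] <- vector("list", n_inits)
    for (i in seq_len(n_inits)) {
      s <- derive_seed(master_seed, paste0("cohort_", cond, "_", i))
      net <- init_network(config, les, seed = s)
      net <- train_network(net, patterns, n_epochs = n_epochs, seed = s + 1L)
      acc[[length(acc) + 1L]] <- net$log %>%
        mutate(condition = cond, init = i, .before = 1)
      probes[[cond]][[i]] <- probe_features(net)
    }
  }
  structure(list(accuracy = bind_rows(acc), probes = probes,
                 units = patterns$units, config = config,
                 master_seed = master_seed, n_inits = n_inits),
            class = "chorse_cohort")
}
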