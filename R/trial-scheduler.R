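# Constraint-satisfying trial schedules: exposure phase, six interleaved
# part-learning / color-memory blocks, and the post-learning test.
#
# Scheduling uses seeded randomized greedy construction with bounded restarts;
# every emitted sequence passes the pure constraint checker with 0 violations.

feature_type_of <- function(role, novel) {
  dplyr::case_when(
    role == "unique" ~ "unique_trained",
    role == "shared" & !novel ~ "shared_trained",
    role == "shared" & novel ~ "shared_novel",
    TRUE ~ NA_character_
  )
}

# Randomized greedy ordering of part trials: no satellite and no part type
# back-to-back. Returns a permutation of rows of `df`.
sample_part_order <- function(df, max_restarts = 10000L) {
  n <- nrow(df)
  for (attempt in seq_len(max_restarts)) {
    rem <- seq_len(n)
    ord <- integer(0)
    last_sat <- ""
    last_type <- ""
    ok <- TRUE
    for (i in seq_len(n)) {
      feas <- rem[df$satellite_id[rem] != last_sat & df$part_type[rem] != last_type]
      if (!length(feas)) {
        ok <- FALSE
        break
      }
      pick <- if (length(feas) == 1L) feas else sample(feas, 1L)
      ord <- c(ord, pick)
      rem <- setdiff(rem, pick)
      last_sat <- df$satellite_id[pick]
      last_type <- df$part_type[pick]
    }
    if (ok) return(ord)
  }
  abort("part-trial scheduling failed after bounded restarts; constraints unsatisfiable?")
}

# Randomized greedy ordering of color trials against a fixed part-trial order:
# the part queried on color trial j must differ from the parts of the three
# most recent part trials (positions j, j-1, j-2).
sample_color_order <- function(df, part_parts, max_restarts = 10000L) {
  n <- nrow(df)
  stopifnot(length(part_parts) == n)
  for (attempt in seq_len(max_restarts)) {
    rem <- seq_len(n)
    ord <- integer(0)
    ok <- TRUE
    for (j in seq_len(n)) {
      recent <- part_parts[max(1L, j - 2L):j]
      feas <- rem[!df$part_id[rem] %in% recent]
      if (!length(feas)) {
        ok <- FALSE
        break
      }
      pick <- if (length(feas) == 1L) feas else sample(feas, 1L)
      ord <- c(ord, pick)
      rem <- setdiff(rem, pick)
    }
    if (ok) return(ord)
  }
  abort("color-trial scheduling failed after bounded restarts; constraints unsatisfiable?")
}

# 4AFC part options: the four parts of the queried type across both
# categories, shuffled; correct_option indexes the queried part.
part_options <- function(set, part_type, part_id) {
  opts <- unique(set$part_id[set$part_type == part_type & !set$novel])
  if (!part_id %in% opts) opts <- c(opts, part_id)
  opts <- sample(opts)
  list(options = opts, correct = match(part_id, opts))
}

color_options <- function() {
  opts <- sample(c("target", "attract", "repel", "orth1", "orth2"))
  list(options = opts, correct = match("target", opts))
}

option_cols <- function(options, n = 5L) {
  out <- rep(NA_character_, n)
  out[seq_along(options)] <- options
  setNames(as.list(out), paste0("option_", seq_len(n)))
}

#' Build the initial exposure phase
#'
#' One color reveal per row. In the Experiment 1 variant every part of every
#' satellite is revealed once per occurrence, so each shared color is seen
#' three times and each unique color once. In the Experiment 2 variant each
#' satellite reveals one unique and one shared color, with the shared
#' assignments forming an exact cover so that every one of the 16 colors is
#' shown exactly once.
#'
#' @param set Trained `satellite_set`.
#' @param assignment `color_assignment` (carried for interface symmetry).
#' @param variant `"exp1"` or `"exp2"`.
#' @param seed Integer RNG seed.
#' @return Tibble of exposure trials.
#' @export
build_exposure <- function(set, assignment, variant = c("exp1", "exp2"), seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(set, "satellite_set"))
  with_seed(seed, {
    sats <- unique(set$satellite_id)
    sat_order <- sample(sats)
    rows <- list()
    if (variant == "exp1") {
      for (s in sat_order) {
        sub <- set[set$satellite_id == s, ]
        sub <- sub[sample(nrow(sub)), ]
        rows[[length(rows) + 1L]] <- sub
      }
    } else {
      # exact cover: per category, match satellites to shared parts they own
      picks <- list()
      for (cat_name in unique(set$category)) {
        cs <- set %>% filter(.data$category == cat_name)
        sat_ids <- unique(cs$satellite_id)
        shared_ids <- unique(cs$part_id[cs$role == "shared"])
        repeat {
          perm <- sample(shared_ids)
          owns <- vapply(seq_along(sat_ids), function(i) {
            perm[i] %in% cs$part_id[cs$satellite_id == sat_ids[i]]
          }, logical(1))
          if (all(owns)) break
        }
        picks[[cat_name]] <- setNames(perm, sat_ids)
      }
      pick_map <- unlist(unname(picks))
      for (s in sat_order) {
        sub <- set[set$satellite_id == s &
                     (set$role == "unique" | set$part_id == pick_map[[s]]), ]
        sub <- sub[sample(nrow(sub)), ]
        rows[[length(rows) + 1L]] <- sub
      }
    }
    out <- bind_rows(rows) %>%
      mutate(phase = "exposure", block = NA_integer_,
             trial_type = "exposure", trial_index = row_number(),
             feature_type = feature_type_of(.data$role, .data$novel),
             feedback = FALSE) %>%
      select("phase", "block", "trial_index", "trial_type", "satellite_id",
             "part_id", "part_type", "role", "feature_type", "feedback")
    out
  })
}

#' Pseudorandomized satellite plan for querying shared parts
#'
#' Per shared part, a length-`n_blocks` sequence of owner satellites in which
#' each of the three owners appears exactly `n_blocks / 3` times, so that by
#' the end of learning all satellites have been used equally often.
#'
#' @param set Trained `satellite_set`.
#' @param n_blocks Number of learning blocks (default 6; must be a multiple of 3).
#' @param seed Integer RNG seed.
#' @return Tibble `part_id`, `block`, `satellite_id`.
#' @export
build_shared_query_plan <- function(set, n_blocks = 6L, seed = 1L) {
  stopifnot(inherits(set, "satellite_set"), n_blocks %% 3L == 0L)
  parts <- part_table(set) %>% filter(.data$role == "shared")
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(parts)), function(i) {
      owners <- parts$owners[[i]]
      seqn <- sample(rep(owners, n_blocks / 3L))
      tibble(part_id = parts$part_id[i], block = seq_len(n_blocks),
             satellite_id = seqn)
    })
  })
}

#' Build one learning block (16 part + 16 color trials, alternating)
#'
#' Each of the 16 parts is queried exactly once on a part trial and once on a
#' color trial. Part trials avoid repeating a satellite or a part type
#' back-to-back; the part tested on each color trial differs from the parts of
#' the three most recent part trials. Shared parts are queried on the
#' satellite given by the shared query plan; with `exp2_decoupling` the color
#' trial may use a different owner than the part trial.
#'
#' @param block_idx Block number 1-6.
#' @param set Trained `satellite_set`.
#' @param assignment `color_assignment`.
#' @param plan Output of [build_shared_query_plan()].
#' @param seed Integer RNG seed.
#' @param exp2_decoupling Allow color-trial satellite to differ from the
#'   part-trial satellite for shared parts (Experiment 2 variant).
#' @param max_restarts Bounded retries for the greedy scheduler.
#' @return Tibble of 32 trials with columns `phase`, `block`, `trial_index`,
#'   `trial_type`, `satellite_id`, `part_id`, `part_type`, `role`,
#'   `feature_type`, `feedback`, `option_1`..`option_5`, `correct_option`.
#' @export
build_learning_block <- function(block_idx, set, assignment, plan, seed = 1L,
                                 exp2_decoupling = FALSE, max_restarts = 10000L) {
  stopifnot(inherits(set, "satellite_set"))
  parts <- part_table(set)
  plan_b <- plan %>% filter(.data$block == block_idx)
  with_seed(seed + block_idx * 1000L, {
    qsat <- vapply(seq_len(nrow(parts)), function(i) {
      if (parts$role[i] == "unique") parts$owners[[i]][1]
      else plan_b$satellite_id[plan_b$part_id == parts$part_id[i]]
    }, character(1))
    pq <- tibble(part_id = parts$part_id, part_type = parts$part_type,
                 role = parts$role, satellite_id = qsat)
    cq <- pq
    if (exp2_decoupling) {
      cq$satellite_id <- vapply(seq_len(nrow(parts)), function(i) {
        if (parts$role[i] == "unique") parts$owners[[i]][1]
        else sample(parts$owners[[i]], 1L)
      }, character(1))
    }
    p_ord <- sample_part_order(pq, max_restarts)
    pq <- pq[p_ord, ]
    c_ord <- sample_color_order(cq, pq$part_id, max_restarts)
    cq <- cq[c_ord, ]

    make_rows <- function(q, type) {
      purrr::map_dfr(seq_len(nrow(q)), function(i) {
        if (type == "part") {
          op <- part_options(set, q$part_type[i], q$part_id[i])
        } else {
          op <- color_options()
        }
        tibble(trial_type = type, satellite_id = q$satellite_id[i],
               part_id = q$part_id[i], part_type = q$part_type[i],
               role = q$role[i],
               feature_type = feature_type_of(q$role[i], FALSE),
               feedback = type == "part",
               !!!option_cols(op$options), correct_option = op$correct)
      })
    }
    p_rows <- make_rows(pq, "part")
    c_rows <- make_rows(cq, "color")
    idx <- order(c(seq_len(16L) * 2L - 1L, seq_len(16L) * 2L))
    out <- bind_rows(p_rows, c_rows)[idx, ] %>%
      mutate(phase = "learning", block = as.integer(block_idx),
             trial_index = row_number()) %>%
      select("phase", "block", "trial_index", dplyr::everything())
    out
  })
}

#' Build all six learning blocks
#'
#' @inheritParams build_learning_block
#' @param n_blocks Number of blocks.
#' @return Tibble of `n_blocks` x 32 trials.
#' @export
build_learning_phase <- function(set, assignment, seed = 1L, n_blocks = 6L,
                                 exp2_decoupling = FALSE) {
  plan <- build_shared_query_plan(set, n_blocks, seed = seed)
  purrr::map_dfr(seq_len(n_blocks), function(b) {
    build_learning_block(b, set, assignment, plan, seed = seed,
                         exp2_decoupling = exp2_decoupling)
  })
}

#' Build the post-learning test (72 part + 72 color trials)
#'
#' Queries are balanced across the three feature types (24 each): unique parts
#' of trained satellites (3 repetitions each), shared parts of trained
#' satellites (once per owner), and shared parts of novel satellites (each
#' novel satellite's three shared parts once). Adjacency constraints match the
#' learning blocks; no feedback is given.
#'
#' @param set Trained `satellite_set`.
#' @param novel_set Novel `satellite_set` from [build_novel_set()].
#' @param assignment `color_assignment`.
#' @param seed Integer RNG seed.
#' @param max_restarts Bounded retries for the greedy scheduler.
#' @return Tibble of 144 alternating trials.
#' @export
build_post_test <- function(set, novel_set, assignment, seed = 1L,
                            max_restarts = 10000L) {
  stopifnot(inherits(set, "satellite_set"), inherits(novel_set, "satellite_set"))
  parts <- part_table(set)
  with_seed(seed + 777L, {
    uq <- parts %>% filter(.data$role == "unique")
    unique_q <- purrr::map_dfr(seq_len(nrow(uq)), function(i) {
      tibble(part_id = uq$part_id[i], part_type = uq$part_type[i],
             role = "unique", satellite_id = rep(uq$owners[[i]][1], 3L),
             feature_type = "unique_trained")
    })
    sq <- parts %>% filter(.data$role == "shared")
    shared_q <- purrr::map_dfr(seq_len(nrow(sq)), function(i) {
      tibble(part_id = sq$part_id[i], part_type = sq$part_type[i],
             role = "shared", satellite_id = sq$owners[[i]],
             feature_type = "shared_trained")
    })
    novel_q <- novel_set %>%
      filter(.data$role == "shared") %>%
      transmute(part_id = .data$part_id, part_type = .data$part_type,
                role = "shared", satellite_id = .data$satellite_id,
                feature_type = "shared_novel")
    queries <- bind_rows(unique_q, shared_q, novel_q)
    stopifnot(nrow(queries) == 72L)

    p_ord <- sample_part_order(queries, max_restarts)
    pq <- queries[p_ord, ]
    c_ord <- sample_color_order(queries, pq$part_id, max_restarts)
    cq <- queries[c_ord, ]

    make_rows <- function(q, type) {
      purrr::map_dfr(seq_len(nrow(q)), function(i) {
        if (type == "part") {
          op <- part_options(set, q$part_type[i], q$part_id[i])
        } else {
          op <- color_options()
        }
        tibble(trial_type = type, satellite_id = q$satellite_id[i],
               part_id = q$part_id[i], part_type = q$part_type[i],
               role = q$role[i], feature_type = q$feature_type[i],
               feedback = FALSE,
               !!!option_cols(op$options), correct_option = op$correct)
      })
    }
    p_rows <- make_rows(pq, "part")
    c_rows <- make_rows(cq, "color")
    n <- nrow(p_rows)
    idx <- order(c(seq_len(n) * 2L - 1L, seq_len(n) * 2L))
    bind_rows(p_rows, c_rows)[idx, ] %>%
      mutate(phase = "post_test", block = NA_integer_,
             trial_index = row_number()) %>%
      select("phase", "block", "trial_index", dplyr::everything())
  })
}

#' @importFrom dplyr transmute
NULL

#' Check a trial sequence against the scheduling constraints
#'
#' Pure validator: alternation of part and color trials, no satellite or part
#' type repeated back-to-back across part trials, the color-trial part absent
#' from the three most recent part trials, and correct option counts (4 for
#' part trials, 5 for color trials).
#'
#' @param trials Trial tibble from the block or post-test builders.
#' @return Tibble of violations (`phase`, `block`, `trial_index`, `rule`);
#'   zero rows when the sequence is valid. Attribute `n_violations`.
#' @export
validate_schedule <- function(trials) {
  viols <- list()
  add <- function(phase, block, idx, rule) {
    viols[[length(viols) + 1L]] <<- tibble(phase = phase, block = block,
                                           trial_index = idx, rule = rule)
  }
  groups <- trials %>%
    filter(.data$trial_type %in% c("part", "color")) %>%
    group_by(.data$phase, .data$block) %>%
    dplyr::group_split()
  for (g in groups) {
    g <- g %>% arrange(.data$trial_index)
    ph <- g$phase[1]
    bl <- g$block[1]
    expect_type <- rep(c("part", "color"), length.out = nrow(g))
    bad <- which(g$trial_type != expect_type)
    for (i in bad) add(ph, bl, g$trial_index[i], "alternation")
    pt <- g %>% filter(.data$trial_type == "part")
    if (nrow(pt) > 1L) {
      rep_sat <- which(pt$satellite_id[-1] == pt$satellite_id[-nrow(pt)]) + 1L
      for (i in rep_sat) add(ph, bl, pt$trial_index[i], "satellite_back_to_back")
      rep_typ <- which(pt$part_type[-1] == pt$part_type[-nrow(pt)]) + 1L
      for (i in rep_typ) add(ph, bl, pt$trial_index[i], "part_type_back_to_back")
    }
    ct <- g %>% filter(.data$trial_type == "color")
    for (j in seq_len(nrow(ct))) {
      recent <- pt$part_id[max(1L, j - 2L):min(j, nrow(pt))]
      if (ct$part_id[j] %in% recent) add(ph, bl, ct$trial_index[j], "color_three_back")
    }
    if (all(c("option_1", "option_5") %in% names(g))) {
      opt_n <- rowSums(!is.na(as.matrix(g[paste0("option_", 1:5)])))
      need <- ifelse(g$trial_type == "part", 4L, 5L)
      for (i in which(opt_n != need)) add(ph, bl, g$trial_index[i], "option_count")
    }
  }
  out <- if (length(viols)) bind_rows(viols) else
    tibble(phase = character(), block = integer(), trial_index = integer(),
           rule = character())
  attr(out, "n_violations") <- nrow(out)
  out
}
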