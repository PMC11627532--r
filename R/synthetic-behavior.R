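# Synthetic participants: a parameterized memory-warping model that turns
# trial schedules into 5AFC color choices and 4AFC part-accuracy records, so
# the behavioral pipeline can be exercised and validated without human data.
# The generative rule: the remembered color is the target displaced `bias`
# CIELAB units toward the category center plus isotropic Gaussian noise; the
# subject picks the nearest of the five options (or guesses with probability
# `lapse`).

expand_trajectory <- function(x, n_blocks) {
  if (length(x) == n_blocks) return(x)
  if (length(x) == 1L) return(rep(x, n_blocks))
  if (length(x) == 2L) return(seq(x[1], x[2], length.out = n_blocks))
  abort("trajectory must have length 1, 2 (start/end), or n_blocks")
}

#' Parameters of a synthetic participant cohort
#'
#' Biases are signed CIELAB units (positive = toward the category center) and
#' may vary over learning blocks; length-2 inputs are linearly interpolated
#' between start and end values. Defaults emulate the qualitative pattern of
#' the behavioral experiments: a stable attraction bias for shared features
#' and a declining one for unique features, part accuracy rising from near
#' chance toward but not reaching ceiling.
#'
#' @param bias_shared,bias_unique Block-wise attraction bias trajectories,
#'   CIELAB units.
#' @param bias_shared_novel Bias for shared features queried on novel
#'   satellites at post-test; defaults to the final shared bias.
#' @param memory_noise_sd SD of the isotropic memory noise, CIELAB units.
#' @param lapse Probability of a uniform random choice.
#' @param part_acc_shared,part_acc_unique Block-wise first-attempt part
#'   accuracy trajectories in `[0, 1]`.
#' @param part_acc_shared_novel Part accuracy for shared features of novel
#'   satellites at post-test.
#' @param subject_sd SD of a per-subject additive offset on the color bias.
#' @param n_blocks Number of learning blocks.
#' @return List of class `participant_params` with expanded trajectories.
#' @export
participant_params <- function(bias_shared = c(2.5, 2.5),
                               bias_unique = c(2.5, 0.5),
                               bias_shared_novel = NULL,
                               memory_noise_sd = 4, lapse = 0.1,
                               part_acc_shared = c(0.55, 0.9),
                               part_acc_unique = c(0.4, 0.9),
                               part_acc_shared_novel = 0.65,
                               subject_sd = 0.5, n_blocks = 6L) {
  stopifnot(memory_noise_sd >= 0, lapse >= 0, lapse <= 1, subject_sd >= 0)
  p <- list(
    bias_shared = expand_trajectory(bias_shared, n_blocks),
    bias_unique = expand_trajectory(bias_unique, n_blocks),
    part_acc_shared = expand_trajectory(part_acc_shared, n_blocks),
    part_acc_unique = expand_trajectory(part_acc_unique, n_blocks),
    memory_noise_sd = memory_noise_sd, lapse = lapse,
    part_acc_shared_novel = part_acc_shared_novel,
    subject_sd = subject_sd, n_blocks = n_blocks)
  p$bias_shared_novel <- if (is.null(bias_shared_novel))
    p$bias_shared[n_blocks] else bias_shared_novel
  stopifnot(all(p$part_acc_shared >= 0 & p$part_acc_shared <= 1),
            all(p$part_acc_unique >= 0 & p$part_acc_unique <= 1))
  structure(p, class = "participant_params")
}

#' Simulate a single 5AFC color choice
#'
#' The internal memory coordinate is `target + bias * u + noise`, where `u`
#' is the unit vector from the target toward the category center and the
#' noise is isotropic Gaussian in the (a*, b*) plane. With probability
#' `lapse` the choice is uniform over the five options; otherwise the option
#' nearest the memory coordinate is chosen, ties broken in random order.
#' Uses the current RNG state.
#'
#' @param foils Five-row `foil_set` slice for one part.
#' @param center Category center `(a, b)`.
#' @param bias Signed bias in CIELAB units (positive = toward center).
#' @param noise_sd Memory noise SD (>= 0).
#' @param lapse Lapse probability.
#' @return Chosen option label.
#' @export
simulate_color_choice <- function(foils, center, bias, noise_sd = 0, lapse = 0) {
  stopifnot(nrow(foils) == 5L, is.finite(bias), noise_sd >= 0)
  tgt <- c(foils$a[foils$option == "target"], foils$b[foils$option == "target"])
  d <- center - tgt
  len <- sqrt(sum(d^2))
  if (len < 1e-9) abort("target coincides with category center")
  u <- d / len
  if (runif(1) < lapse) return(sample(foils$option, 1L))
  m <- tgt + bias * u + rnorm(2, 0, noise_sd)
  dist2 <- (foils$a - m[1])^2 + (foils$b - m[2])^2
  ord <- sample(nrow(foils))
  foils$option[ord][which.min(dist2[ord])]
}

bias_for <- function(params, feature_type, block) {
  block <- ifelse(is.na(block), params$n_blocks, block)
  dplyr::case_when(
    feature_type == "shared_trained" ~ params$bias_shared[block],
    feature_type == "unique_trained" ~ params$bias_unique[block],
    feature_type == "shared_novel" ~ params$bias_shared_novel,
    TRUE ~ 0)
}

part_acc_for <- function(params, feature_type, block) {
  block <- ifelse(is.na(block), params$n_blocks, block)
  dplyr::case_when(
    feature_type == "shared_trained" ~ params$part_acc_shared[block],
    feature_type == "unique_trained" ~ params$part_acc_unique[block],
    feature_type == "shared_novel" ~ params$part_acc_shared_novel,
    TRUE ~ 0.25)
}

#' Simulate a cohort of synthetic participants
#'
#' Applies the memory-warping choice model to every color trial and a
#' Bernoulli accuracy model to every part trial of a schedule, for
#' `n_subjects` subjects sharing the cohort parameters (plus a per-subject
#' bias offset with SD `subject_sd`). Deterministic given the seed.
#'
#' @param trials Trial schedule tibble (exposure rows pass through with no
#'   choice).
#' @param assignment The `color_assignment` used to derive foil geometry.
#' @param params A `participant_params`.
#' @param n_subjects Number of subjects.
#' @param seed Integer RNG seed.
#' @return Response tibble: `subject_id`, `phase`, `block`, `trial_index`,
#'   `trial_type`, `satellite_id`, `part_id`, `feature_type`,
#'   `chosen_option`, `correct`, `timed_out`, `rt`.
#' @export
simulate_cohort <- function(trials, assignment, params = participant_params(),
                            n_subjects = 85L, seed = 1L) {
  stopifnot(inherits(params, "participant_params"))
  foils <- make_foils(assignment)
  opt_levels <- c("target", "attract", "repel", "orth1", "orth2")
  foil_wide <- foils %>%
    select("part_id", "option", "a", "b") %>%
    tidyr::pivot_wider(names_from = "option", values_from = c("a", "b"))
  with_seed(seed, {
    subj <- sprintf("s%03d", seq_len(n_subjects))
    off <- rnorm(n_subjects, 0, params$subject_sd)

    ct <- trials %>% filter(.data$trial_type == "color") %>%
      left_join(foil_wide, by = "part_id")
    out_color <- NULL
    if (nrow(ct)) {
      cen <- t(vapply(ct$part_id, function(pid) {
        category_center(assignment, assignment$category[assignment$part_id == pid])
      }, numeric(2)))
      ua <- cen[, 1] - ct$a_target
      ub <- cen[, 2] - ct$b_target
      len <- sqrt(ua^2 + ub^2)
      ua <- ua / len
      ub <- ub / len
      base <- bias_for(params, ct$feature_type, ct$block)
      Tn <- nrow(ct)
      mu_a <- ct$a_target + base * ua
      mu_b <- ct$b_target + base * ub
      ma <- matrix(mu_a, n_subjects, Tn, byrow = TRUE) + outer(off, ua) +
        matrix(rnorm(n_subjects * Tn, 0, params$memory_noise_sd), n_subjects)
      mb <- matrix(mu_b, n_subjects, Tn, byrow = TRUE) + outer(off, ub) +
        matrix(rnorm(n_subjects * Tn, 0, params$memory_noise_sd), n_subjects)
      best <- matrix(1L, n_subjects, Tn)
      bestd <- (sweep(ma, 2, ct$a_target))^2 + (sweep(mb, 2, ct$b_target))^2
      for (k in 2:5) {
        oa <- ct[[paste0("a_", opt_levels[k])]]
        ob <- ct[[paste0("b_", opt_levels[k])]]
        dk <- (sweep(ma, 2, oa))^2 + (sweep(mb, 2, ob))^2
        upd <- dk < bestd
        best[upd] <- k
        bestd[upd] <- dk[upd]
      }
      lap <- matrix(runif(n_subjects * Tn) < params$lapse, n_subjects)
      if (any(lap)) best[lap] <- sample.int(5L, sum(lap), replace = TRUE)
      # as.vector(best) runs subjects fastest within trial columns
      out_color <- tibble(
        subject_id = rep(subj, times = Tn),
        trial_key = rep(seq_len(Tn), each = n_subjects),
        chosen_option = opt_levels[as.vector(best)]) %>%
        left_join(ct %>% mutate(trial_key = row_number()) %>%
                    select("trial_key", "phase", "block", "trial_index",
                           "trial_type", "satellite_id", "part_id",
                           "feature_type"),
                  by = "trial_key") %>%
        mutate(correct = .data$chosen_option == "target") %>%
        select(-"trial_key")
    }

    pt <- trials %>% filter(.data$trial_type == "part")
    out_part <- NULL
    if (nrow(pt)) {
      pacc <- part_acc_for(params, pt$feature_type, pt$block)
      Tn <- nrow(pt)
      hit <- matrix(runif(n_subjects * Tn), n_subjects) <
        matrix(pacc, n_subjects, Tn, byrow = TRUE)
      out_part <- tibble(
        subject_id = rep(subj, times = Tn),
        trial_key = rep(seq_len(Tn), each = n_subjects),
        correct = as.vector(hit)) %>%
        left_join(pt %>% mutate(trial_key = row_number()) %>%
                    select("trial_key", "phase", "block", "trial_index",
                           "trial_type", "satellite_id", "part_id",
                           "feature_type"),
                  by = "trial_key") %>%
        mutate(chosen_option = ifelse(.data$correct, .data$part_id, NA_character_)) %>%
        select(-"trial_key")
    }

    et <- trials %>% filter(!.data$trial_type %in% c("part", "color"))
    out_exp <- NULL
    if (nrow(et)) {
      out_exp <- tidyr::crossing(subject_id = subj,
                                 et %>% select("phase", "block", "trial_index",
                                               "trial_type", "satellite_id",
                                               "part_id", "feature_type")) %>%
        mutate(chosen_option = NA_character_, correct = NA)
    }

    bind_rows(out_color, out_part, out_exp) %>%
      mutate(timed_out = FALSE, rt = NA_real_) %>%
      arrange(.data$subject_id, .data$phase, .data$block, .data$trial_index)
  })
}
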