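# Behavioral measures: attraction-bias scores (per-trial codes +1 attract,
# -1 repel, 0 target/orthogonal, averaged), foil-choice profiles, accuracies,
# classical tests on subject-level scores, and the power/sample-size
# computation via the noncentral t distribution.

code_response <- function(chosen_option) {
  dplyr::case_when(chosen_option == "attract" ~ 1,
                   chosen_option == "repel" ~ -1,
                   TRUE ~ 0)
}

drop_timeouts_if <- function(responses, drop_timeouts) {
  if (drop_timeouts && "timed_out" %in% names(responses))
    responses %>% filter(!.data$timed_out %in% TRUE)
  else responses
}

#' Color attraction bias scores
#'
#' Codes each color-trial response (+1 attract foil, -1 repel foil, 0 target
#' or orthogonal foil) and averages within groups. Positive scores indicate
#' memory warped toward the category's average color.
#'
#' @param responses Response tibble with at least `trial_type` and
#'   `chosen_option`.
#' @param ... Grouping columns (tidy-select), e.g. `subject_id`,
#'   `feature_type`, `block`.
#' @param drop_timeouts Drop records flagged `timed_out` (default TRUE).
#' @return Tibble of class `bias_score` with `score` in `[-1, 1]` and
#'   `n_trials` per group.
#' @export
#' @examples
#' tbl <- tibble::tibble(subject_id = "s1", trial_type = "color",
#'                       chosen_option = c("attract", "attract", "repel", "target"))
#' attraction_bias(tbl, subject_id)  # (1 + 1 - 1 + 0) / 4 = 0.25
attraction_bias <- function(responses, ..., drop_timeouts = TRUE) {
  cr <- drop_timeouts_if(responses, drop_timeouts) %>%
    filter(.data$trial_type == "color")
  if (!nrow(cr)) {
    warn("no color trials; returning empty score table")
    return(tibble(score = numeric(), n_trials = integer()))
  }
  out <- cr %>%
    mutate(.code = code_response(.data$chosen_option)) %>%
    group_by(...) %>%
    summarise(score = mean(.data$.code), n_trials = dplyr::n(), .groups = "drop")
  class(out) <- c("bias_score", class(out))
  out
}

#' Foil-choice proportions
#'
#' Empirical choice proportions over target, attract, repel, and orthogonal
#' options (the two side foils pooled). Proportions sum to 1 within each
#' group.
#'
#' @inheritParams attraction_bias
#' @return Tibble with columns `p_target`, `p_attract`, `p_repel`,
#'   `p_orthogonal`, `n_trials`.
#' @export
choice_profile <- function(responses, ..., drop_timeouts = TRUE) {
  cr <- drop_timeouts_if(responses, drop_timeouts) %>%
    filter(.data$trial_type == "color")
  cr %>%
    group_by(...) %>%
    summarise(p_target = mean(.data$chosen_option == "target"),
              p_attract = mean(.data$chosen_option == "attract"),
              p_repel = mean(.data$chosen_option == "repel"),
              p_orthogonal = mean(.data$chosen_option %in% c("orth1", "orth2")),
              n_trials = dplyr::n(), .groups = "drop")
}

#' Response accuracy
#'
#' Mean correctness per group: first-attempt part choice for part trials,
#' target color choice for color trials. Chance is 1/4 for the 4AFC part
#' trials and 1/5 for the 5AFC color trials.
#'
#' @inheritParams attraction_bias
#' @param trial_type `"part"` or `"color"`.
#' @return Tibble with `accuracy` and `n_trials` per group.
#' @export
response_accuracy <- function(responses, trial_type = c("part", "color"), ...,
                              drop_timeouts = TRUE) {
  trial_type <- match.arg(trial_type)
  tt <- trial_type
  sub <- drop_timeouts_if(responses, drop_timeouts) %>%
    filter(.data$trial_type == tt)
  sub %>%
    group_by(...) %>%
    summarise(accuracy = mean(.data$correct), n_trials = dplyr::n(),
              .groups = "drop")
}

#' One-sample t test (direct formula)
#'
#' @param x Numeric scores (n >= 2).
#' @param mu Null value.
#' @return Tibble: `estimate`, `statistic`, `df`, `p.value`, `cohens_d`,
#'   `degenerate` (TRUE when the scores are constant and t is infinite).
#' @export
t_one_sample <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) abort("need at least two observations")
  n <- length(x)
  s <- sd(x)
  t <- if (s == 0) {
    if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
  } else (mean(x) - mu) / (s / sqrt(n))
  tibble(estimate = mean(x), statistic = t, df = n - 1,
         p.value = if (is.finite(t)) 2 * pt(-abs(t), n - 1) else 0,
         cohens_d = if (s == 0) NA_real_ else (mean(x) - mu) / s,
         degenerate = !is.finite(t))
}

#' Paired t test (direct formula)
#'
#' @param x,y Paired numeric scores.
#' @return As [t_one_sample()] on the differences.
#' @export
t_paired <- function(x, y) {
  out <- t_one_sample(x - y)
  out
}

#' Classical tests on subject-level bias scores
#'
#' One-sample t against zero overall and within each feature type, plus the
#' paired shared-vs-unique contrast, with optional Benjamini-Hochberg FDR
#' adjustment across the reported family.
#'
#' @param scores A `bias_score` tibble with `subject_id`, `feature_type`,
#'   `score` (one row per subject x feature type).
#' @param fdr Apply BH adjustment across the returned p values.
#' @return Tibble of class `bias_tests`: `term`, `estimate`, `statistic`,
#'   `df`, `p.value`, `cohens_d` (and `p.adjusted` when `fdr = TRUE`).
#' @export
bias_score_tests <- function(scores, fdr = FALSE) {
  stopifnot(all(c("subject_id", "feature_type", "score") %in% names(scores)))
  overall <- scores %>%
    group_by(.data$subject_id) %>%
    summarise(score = mean(.data$score), .groups = "drop")
  rows <- list(t_one_sample(overall$score) %>% mutate(term = "overall_vs_0"))
  for (ft in sort(unique(scores$feature_type))) {
    rows[[length(rows) + 1L]] <-
      t_one_sample(scores$score[scores$feature_type == ft]) %>%
      mutate(term = paste0(ft, "_vs_0"))
  }
  if (all(c("shared_trained", "unique_trained") %in% scores$feature_type)) {
    wide <- scores %>%
      filter(.data$feature_type %in% c("shared_trained", "unique_trained")) %>%
      tidyr::pivot_wider(id_cols = "subject_id", names_from = "feature_type",
                         values_from = "score")
    rows[[length(rows) + 1L]] <-
      t_paired(wide$shared_trained, wide$unique_trained) %>%
      mutate(term = "shared_minus_unique")
  }
  out <- bind_rows(rows) %>% select("term", dplyr::everything())
  if (fdr) out$p.adjusted <- adjust_fdr(out$p.value)
  class(out) <- c("bias_tests", class(out))
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Vector of p values.
#' @return Adjusted p values.
#' @export
adjust_fdr <- function(p) p.adjust(p, method = "BH")

#' Minimum sample size for a one-sample (paired) t test
#'
#' Smallest n such that a t test at level `alpha` with noncentrality
#' `d * sqrt(n)` reaches the target power, found by iterating n against the
#' noncentral t distribution. The default is one-tailed.
#'
#' @param d Cohen's d effect size (nonzero).
#' @param power Target power in (0, 1).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @param n_max Search bound.
#' @return Integer sample size.
#' @export
#' @examples
#' required_sample_size(d = 0.24, power = 0.80)  # 109
required_sample_size <- function(d, power = 0.80, alpha = 0.05, tails = 1L,
                                 n_max = 1e6L) {
  stopifnot(d != 0, power > 0, power < 1, alpha > 0, alpha < 1,
            tails %in% c(1L, 2L))
  d <- abs(d)
  a <- alpha / tails
  for (n in 2:n_max) {
    crit <- qt(1 - a, df = n - 1)
    pw <- pt(crit, df = n - 1, ncp = d * sqrt(n), lower.tail = FALSE)
    if (pw >= power) return(as.integer(n))
  }
  abort("target power unreachable within n_max")
}
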