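# broom-style tidiers for the fitted/result objects.

#' Tidy the shared-vs-unique contrast
#'
#' @param x A `catwarp_contrast`.
#' @param ... Unused.
#' @return Tibble with one row per test: the per-condition paired t tests and
#'   the ANOVA terms.
#' @method tidy catwarp_contrast
#' @export
tidy.catwarp_contrast <- function(x, ...) {
  bind_rows(
    x$t_tests %>%
      mutate(term = paste0("paired_t_", .data$condition)) %>%
      select("term", "estimate", "statistic", "df", "p.value", "cohens_d"),
    x$anova %>%
      filter(.data$term != "residuals") %>%
      mutate(term = paste0("anova_", .data$term)) %>%
      select("term", "statistic", "df", "p.value"))
}

#' One-row summary of the contrast: the pathway-by-role interaction
#'
#' @param x A `catwarp_contrast`.
#' @param ... Unused.
#' @return One-row tibble: interaction `statistic`, `df1`, `df2`, `p.value`.
#' @method glance catwarp_contrast
#' @export
glance.catwarp_contrast <- function(x, ...) {
  ia <- x$anova %>% filter(.data$term == "condition:role")
  res <- x$anova %>% filter(.data$term == "residuals")
  tibble(statistic = ia$statistic, df1 = ia$df, df2 = res$df,
         p.value = ia$p.value)
}

#' Tidy a trained network's learning log
#'
#' @param x A `chorse_network` (after [train_network()]).
#' @param ... Unused.
#' @return The per-epoch accuracy tibble.
#' @method tidy chorse_network
#' @export
tidy.chorse_network <- function(x, ...) {
  if (is.null(x$log)) abort("network has no training log; call train_network()")
  x$log
}

#' One-row summary of a trained network
#'
#' @param x A `chorse_network`.
#' @param ... Unused.
#' @return Tibble: layer sizes, lesion flags, epochs trained, final accuracy.
#' @method glance chorse_network
#' @export
glance.chorse_network <- function(x, ...) {
  tibble(n_ec = x$n_ec, n_dg = x$config$n_dg, n_ca3 = x$config$n_ca3,
         n_ca1 = x$config$n_ca1, msp_lesioned = x$lesions$msp,
         tsp_lesioned = x$lesions$tsp,
         epochs_trained = if (is.null(x$log)) 0L else max(x$log$epoch),
         final_accuracy = if (is.null(x$log)) NA_real_ else
           x$log$accuracy[which.max(x$log$epoch)])
}

#' Tidy a cohort's accuracy log
#'
#' @param x A `chorse_cohort`.
#' @param ... Unused.
#' @return Tibble `condition`, `init`, `epoch`, `accuracy`.
#' @method tidy chorse_cohort
#' @export
tidy.chorse_cohort <- function(x, ...) x$accuracy

#' Per-condition summary of a cohort
#'
#' @param x A `chorse_cohort`.
#' @param ... Unused.
#' @return Tibble with per-condition mean final-epoch accuracy.
#' @method glance chorse_cohort
#' @export
glance.chorse_cohort <- function(x, ...) {
  x$accuracy %>%
    filter(.data$epoch == max(.data$epoch)) %>%
    group_by(.data$condition) %>%
    summarise(n_inits = dplyr::n(), final_accuracy = mean(.data$accuracy),
              .groups = "drop")
}

#' Tidy an MDS embedding
#'
#' @param x A `catwarp_mds`.
#' @param ... Unused.
#' @return The coordinates tibble with centroid distances.
#' @method tidy catwarp_mds
#' @export
tidy.catwarp_mds <- function(x, ...) x$coords
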