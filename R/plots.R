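# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_path annotate labs
#'   facet_wrap stat_summary position_jitter theme_minimal coord_equal
NULL

#' Plot a color assignment in the (a*, b*) plane
#'
#' @param object A `color_assignment`.
#' @param show_foils Overlay the 5AFC foil sets.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot color_assignment
#' @export
autoplot.color_assignment <- function(object, show_foils = FALSE, ...) {
  centers <- attr(object, "centers")
  cen <- tibble(category = names(centers),
                a = vapply(centers, `[[`, numeric(1), "a"),
                b = vapply(centers, `[[`, numeric(1), "b"))
  p <- ggplot(object, aes(x = .data$a, y = .data$b)) +
    geom_point(aes(shape = .data$role, colour = .data$category), size = 3) +
    geom_point(data = cen, shape = 4, size = 3) +
    coord_equal() +
    labs(x = "a*", y = "b*",
         title = "Part colors on the CIELAB category circles (L* = 60)") +
    theme_minimal()
  if (show_foils) {
    f <- make_foils(object) %>% filter(.data$option != "target")
    p <- p + geom_point(data = f, aes(colour = .data$category),
                        size = 1, alpha = 0.5)
  }
  p
}

#' Plot cohort reconstruction accuracy across epochs
#'
#' @param object A `chorse_cohort`.
#' @param ... Unused.
#' @return A ggplot of mean accuracy per epoch and condition.
#' @method autoplot chorse_cohort
#' @export
autoplot.chorse_cohort <- function(object, ...) {
  object$accuracy %>%
    group_by(.data$condition, .data$epoch) %>%
    summarise(accuracy = mean(.data$accuracy), .groups = "drop") %>%
    ggplot(aes(x = .data$epoch, y = .data$accuracy,
               colour = .data$condition)) +
    geom_line() + geom_point() +
    labs(x = "Training epoch", y = "Reconstruction accuracy") +
    theme_minimal()
}

#' Plot per-init Fisher-Z integration by role and condition
#'
#' @param object A `catwarp_rsa` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot catwarp_rsa
#' @export
autoplot.catwarp_rsa <- function(object, ...) {
  rsa_role_means(object) %>%
    ggplot(aes(x = .data$role, y = .data$z, colour = .data$role)) +
    geom_point(position = position_jitter(width = 0.15), alpha = 0.5) +
    stat_summary(fun = mean, geom = "point", size = 4, shape = 18,
                 colour = "black") +
    facet_wrap(~condition) +
    labs(y = "Mean within-category Fisher-Z", x = "Feature role") +
    theme_minimal()
}

#' Plot an MDS embedding of feature representations
#'
#' @param object A `catwarp_mds`.
#' @param ... Unused.
#' @return A ggplot; the cross marks the category centroid.
#' @method autoplot catwarp_mds
#' @export
autoplot.catwarp_mds <- function(object, ...) {
  centroid <- tibble(x = mean(object$coords$x), y = mean(object$coords$y))
  ggplot(object$coords, aes(x = .data$x, y = .data$y,
                            colour = .data$role)) +
    geom_point(size = 3) +
    geom_point(data = centroid, shape = 4, size = 4, colour = "grey40") +
    coord_equal() +
    labs(x = "MDS 1", y = "MDS 2") +
    theme_minimal()
}

#' Plot attraction-bias scores across blocks
#'
#' @param scores Output of [attraction_bias()] grouped by `feature_type` and
#'   `block` (and usually `subject_id`).
#' @return A ggplot of mean score per block and feature type.
#' @export
plot_bias_blocks <- function(scores) {
  scores %>%
    group_by(.data$feature_type, .data$block) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    ggplot(aes(x = .data$block, y = .data$score,
               colour = .data$feature_type)) +
    geom_line() + geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "Learning block", y = "Attraction bias score") +
    theme_minimal()
}
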