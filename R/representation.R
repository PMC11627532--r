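# Feature-level representational similarity analysis of CA1 initial
# responses: within-category Pearson correlations averaged per feature and
# Fisher-Z transformed, the shared-vs-unique pathway contrast, and classical
# multidimensional scaling of the feature similarity structure.

#' Fisher-Z transform with clipping
#'
#' atanh of r after clipping |r| at `1 - clip` so degenerate identical
#' vectors (which occur in untrained networks) stay finite.
#'
#' @param r Correlation(s).
#' @param clip Clipping margin below 1.
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r, clip = 1e-7) {
  atanh(pmax(pmin(r, 1 - clip), -1 + clip))
}

#' Feature-level RSA of a probe matrix
#'
#' For each feature, computes the Pearson correlation of its CA1 initial-
#' response vector with every other same-category feature, averages those
#' correlations, and Fisher-Z transforms the mean. Self-pairs and
#' cross-category pairs are excluded; zero-variance probe vectors are dropped
#' with a warning.
#'
#' @param probe_matrix Features x CA1-units matrix (one row per probed unit).
#' @param units Unit metadata tibble (from a `pattern_set`): columns `unit`,
#'   `category`, `unit_type`, `role`.
#' @param features `"all"` uses every feature of a category (class, codes,
#'   parts; 13 per category); `"parts"` restricts to the 16 part units.
#' @return Tibble: `unit`, `category`, `unit_type`, `role`, `mean_r`, `z`.
#' @export
feature_rsa <- function(probe_matrix, units, features = c("all", "parts")) {
  features <- match.arg(features)
  keep <- if (features == "parts") units$unit_type == "part" else rep(TRUE, nrow(units))
  meta <- units[keep, ]
  X <- probe_matrix[meta$unit, , drop = FALSE]
  v <- apply(X, 1, stats::var)
  if (any(v == 0)) {
    warn(sprintf("%d zero-variance probe vector(s) excluded from RSA", sum(v == 0)))
    meta <- meta[v > 0, ]
    X <- X[v > 0, , drop = FALSE]
  }
  if (nrow(X) < 2L) abort("need at least two probe vectors with variance")
  R <- stats::cor(t(X))
  purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    same <- which(meta$category == meta$category[i])
    same <- setdiff(same, i)
    if (!length(same)) return(NULL)
    mr <- mean(R[i, same])
    tibble(unit = meta$unit[i], category = meta$category[i],
           unit_type = meta$unit_type[i], role = meta$role[i],
           mean_r = mr, z = fisher_z(mr))
  })
}

#' Per-init RSA over a trained cohort
#'
#' Applies [feature_rsa()] to every initialization's probe matrix in every
#' condition.
#'
#' @param cohort A `chorse_cohort`.
#' @param features Passed to [feature_rsa()].
#' @return Tibble of class `catwarp_rsa`: `condition`, `init`, plus the
#'   [feature_rsa()] columns.
#' @export
cohort_rsa <- function(cohort, features = c("all", "parts")) {
  stopifnot(inherits(cohort, "chorse_cohort"))
  features <- match.arg(features)
  out <- purrr::map_dfr(names(cohort$probes), function(cond) {
    purrr::map_dfr(seq_along(cohort$probes[[cond]]), function(i) {
      feature_rsa(cohort$probes[[cond]][[i]], cohort$units, features) %>%
        mutate(condition = cond, init = i, .before = 1)
    })
  })
  class(out) <- c("catwarp_rsa", class(out))
  out
}

#' Per-init mean Fisher-Z by feature role
#'
#' Averages the per-feature Z scores of the shared and unique part features
#' within each initialization and condition.
#'
#' @param rsa A `catwarp_rsa` tibble (or any tibble with `condition`, `init`,
#'   `unit_type`, `role`, `z`).
#' @return Tibble: `condition`, `init`, `role`, `z`.
#' @export
rsa_role_means <- function(rsa) {
  rsa %>%
    filter(.data$unit_type == "part") %>%
    group_by(.data$condition, .data$init, .data$role) %>%
    summarise(z = mean(.data$z), .groups = "drop")
}

# Direct-formula paired t test (df = n - 1), two-tailed p, Cohen's d.
# Zero-variance differences: t = 0 when all differences vanish, +/-Inf for a
# constant nonzero difference.
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  n <- length(d)
  sdd <- sd(d)
  t <- if (sdd == 0) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (sdd / sqrt(n))
  tibble(estimate = mean(d), statistic = t, df = n - 1,
         p.value = if (is.finite(t)) 2 * pt(-abs(t), n - 1) else 0,
         cohens_d = if (sdd == 0) NA_real_ else mean(d) / sdd)
}

# Direct-formula balanced two-way ANOVA with interaction from a long table
# with factors f1, f2 and response y; returns the classical SS decomposition.
anova_two_way <- function(y, f1, f2) {
  f1 <- factor(f1)
  f2 <- factor(f2)
  n <- length(y)
  a <- nlevels(f1)
  b <- nlevels(f2)
  r <- n / (a * b)
  if (r != floor(r)) abort("unbalanced inputs: equal cell sizes required")
  gm <- mean(y)
  m1 <- tapply(y, f1, mean)
  m2 <- tapply(y, f2, mean)
  mc <- tapply(y, list(f1, f2), mean)
  ss1 <- b * r * sum((m1 - gm)^2)
  ss2 <- a * r * sum((m2 - gm)^2)
  ssc <- r * sum((mc - gm)^2)
  ssi <- ssc - ss1 - ss2
  sst <- sum((y - gm)^2)
  sse <- sst - ssc
  df1 <- a - 1
  df2 <- b - 1
  dfi <- df1 * df2
  dfe <- n - a * b
  mse <- sse / dfe
  tibble(term = c(deparse(substitute(f1)), deparse(substitute(f2)),
                  "interaction", "residuals"),
         df = c(df1, df2, dfi, dfe),
         sumsq = c(ss1, ss2, ssi, sse),
         statistic = c(ss1 / df1 / mse, ss2 / df2 / mse, ssi / dfi / mse, NA),
         p.value = c(stats::pf(ss1 / df1 / mse, df1, dfe, lower.tail = FALSE),
                     stats::pf(ss2 / df2 / mse, df2, dfe, lower.tail = FALSE),
                     stats::pf(ssi / dfi / mse, dfi, dfe, lower.tail = FALSE),
                     NA))
}

#' Shared vs unique integration contrast across pathway lesions
#'
#' Paired t test (shared minus unique per initialization) within each lesion
#' condition, and the two-way ANOVA (condition x feature role, initialization
#' as the observational unit) whose interaction tests whether the shared-
#' unique gap differs between pathways. For 50 initializations in two
#' conditions the interaction has df (1, 196). Formulas are computed
#' directly from the sums of squares.
#'
#' @param role_means Output of [rsa_role_means()] (conditions to contrast
#'   must each have both roles for every init).
#' @param conditions The two conditions entering the ANOVA.
#' @return Object of class `catwarp_contrast` with elements `t_tests`
#'   (per-condition paired t) and `anova`.
#' @export
shared_vs_unique_contrast <- function(role_means,
                                      conditions = c("msp_only", "tsp_only")) {
  rm <- role_means %>% filter(.data$condition %in% conditions)
  wide <- rm %>% tidyr::pivot_wider(names_from = "role", values_from = "z")
  if (anyNA(wide$shared) || anyNA(wide$unique)) abort("unbalanced inputs")
  counts <- wide %>% count(.data$condition)
  if (length(unique(counts$n)) != 1L) abort("unbalanced inputs")
  t_tests <- wide %>%
    group_by(.data$condition) %>%
    dplyr::group_modify(~ paired_t(.x$shared, .x$unique)) %>%
    ungroup()
  av <- anova_two_way(rm$z, rm$condition, rm$role) %>%
    mutate(term = c("condition", "role", "condition:role", "residuals"))
  structure(list(t_tests = t_tests, anova = av, conditions = conditions),
            class = "catwarp_contrast")
}

#' @export
print.catwarp_contrast <- function(x, ...) {
  cat("Shared vs unique feature integration contrast\n\nPaired t tests:\n")
  print(x$t_tests)
  cat("\nTwo-way ANOVA (condition x role):\n")
  print(x$anova)
  invisible(x)
}

#' Average feature similarity matrices across initializations
#'
#' Builds the per-init feature x feature correlation matrix of CA1 initial
#' responses within one condition, restricted to one category's features,
#' aligned on canonical feature slots and averaged across initializations and
#' the two categories.
#'
#' @param cohort A `chorse_cohort`.
#' @param condition Condition to extract.
#' @param features `"all"` or `"parts"`.
#' @return List: `similarity` (averaged correlation matrix), `roles`, `labels`
#'   (canonical slot names shared by the two categories).
#' @export
cohort_similarity <- function(cohort, condition, features = c("all", "parts")) {
  features <- match.arg(features)
  units <- cohort$units
  mats <- list()
  for (cat_name in unique(units$category)) {
    keep <- units$category == cat_name
    if (features == "parts") keep <- keep & units$unit_type == "part"
    meta <- units[keep, ]
    slot <- paste0(meta$unit_type,
                   ifelse(meta$unit_type == "part",
                          paste0("_", meta$role, "_", meta$part_type),
                          paste0("_", seq_len(nrow(meta)))))
    for (P in cohort$probes[[condition]]) {
      X <- P[meta$unit, , drop = FALSE]
      R <- suppressWarnings(stats::cor(t(X)))
      R[is.na(R)] <- 0
      rownames(R) <- colnames(R) <- slot
      ord <- order(slot)
      mats[[length(mats) + 1L]] <- R[ord, ord]
    }
  }
  avg <- Reduce(`+`, mats) / length(mats)
  slot_sorted <- rownames(avg)
  roles <- ifelse(grepl("^part_shared", slot_sorted), "shared",
                  ifelse(grepl("^part_unique", slot_sorted), "unique", "other"))
  list(similarity = avg, roles = roles, labels = slot_sorted)
}

#' Classical MDS embedding of feature representations
#'
#' Converts an averaged similarity (correlation) matrix to distances
#' (`1 - r`), embeds with classical metric MDS in 2D, and reports each
#' feature's distance to the category centroid (the mean embedded coordinate)
#' along with per-role mean centroid distances.
#'
#' @param similarity Symmetric similarity matrix, or the list returned by
#'   [cohort_similarity()].
#' @param roles Feature roles (ignored when `similarity` carries them).
#' @return List of class `catwarp_mds`: `coords` tibble (`feature`, `role`,
#'   `x`, `y`, `dist_center`), `role_distance` tibble.
#' @export
mds_embed <- function(similarity, roles = NULL) {
  if (is.list(similarity) && !is.matrix(similarity)) {
    roles <- similarity$roles
    similarity <- similarity$similarity
  }
  if (!isSymmetric(unname(similarity), tol = 1e-8)) abort("similarity matrix must be symmetric")
  D <- 1 - similarity
  diag(D) <- 0
  # rank-deficient configurations (e.g. identical vectors) embed in fewer
  # than two dimensions; pad with zeros rather than warn
  xy <- suppressWarnings(cmdscale(stats::as.dist(D), k = 2))
  if (ncol(xy) < 2) xy <- cbind(xy, matrix(0, nrow(D), 2 - ncol(xy)))
  centroid <- colMeans(xy)
  dist_center <- sqrt(rowSums(sweep(xy, 2, centroid)^2))
  labels <- rownames(similarity)
  if (is.null(labels)) labels <- paste0("f", seq_len(nrow(similarity)))
  if (is.null(roles)) roles <- rep("feature", nrow(similarity))
  coords <- tibble(feature = labels, role = roles,
                   x = xy[, 1], y = xy[, 2], dist_center = dist_center)
  role_distance <- coords %>%
    group_by(.data$role) %>%
    summarise(mean_dist = mean(.data$dist_center), .groups = "drop")
  structure(list(coords = coords, role_distance = role_distance),
            class = "catwarp_mds")
}
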