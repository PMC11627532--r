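color_tbl <- function(choices, subject = "s1") {
  tibble::tibble(subject_id = subject, trial_type = "color",
                 chosen_option = choices, timed_out = FALSE)
}

test_that("attraction bias codes responses +1 / 0 / -1 and averages", {
  expect_equal(attraction_bias(color_tbl(rep("attract", 4)))$score, 1)
  expect_equal(attraction_bias(color_tbl(c("attract", "attract", "repel",
                                           "target")))$score, 0.25)
  expect_equal(attraction_bias(color_tbl(c("orth1", "orth2", "target")))$score, 0)
  # large uniform table: score near 0 by code symmetry
  set.seed(5)
  unif <- color_tbl(sample(c("target", "attract", "repel", "orth1", "orth2"),
                           20000, replace = TRUE))
  expect_lt(abs(attraction_bias(unif)$score), 0.02)
  # timed-out records are dropped by default
  tt <- color_tbl(c("attract", "repel"))
  tt$timed_out <- c(FALSE, TRUE)
  expect_equal(attraction_bias(tt)$score, 1)
  expect_equal(attraction_bias(tt, drop_timeouts = FALSE)$score, 0)
  expect_warning(attraction_bias(color_tbl(character(0))), "no color trials")
})

test_that("choice profiles pool orthogonal foils and sum to one", {
  p <- choice_profile(color_tbl(rep("target", 5)))
  expect_equal(c(p$p_target, p$p_attract, p$p_repel, p$p_orthogonal),
               c(1, 0, 0, 0))
  p2 <- choice_profile(color_tbl(c("target", "attract", "repel", "orth1",
                                   "orth2")))
  expect_equal(c(p2$p_target, p2$p_attract, p2$p_repel, p2$p_orthogonal),
               c(0.2, 0.2, 0.2, 0.4))
  expect_equal(p2$p_target + p2$p_attract + p2$p_repel + p2$p_orthogonal, 1,
               tolerance = 1e-9)
})

test_that("bias score equals P(attract) - P(repel) on arbitrary tables", {
  set.seed(7)
  tbl <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:6), each = 50),
    feature_type = sample(c("shared_trained", "unique_trained"), 300, TRUE),
    trial_type = "color",
    chosen_option = sample(c("target", "attract", "repel", "orth1", "orth2"),
                           300, TRUE),
    timed_out = FALSE)
  b <- attraction_bias(tbl, subject_id, feature_type)
  p <- choice_profile(tbl, subject_id, feature_type)
  j <- dplyr::left_join(b, p, by = c("subject_id", "feature_type"))
  expect_equal(j$score, j$p_attract - j$p_repel, tolerance = 1e-9)
})

test_that("accuracy summaries and chance references", {
  tbl <- tibble::tibble(subject_id = "s1",
                        trial_type = rep(c("part", "color"), each = 4),
                        correct = c(TRUE, TRUE, FALSE, FALSE,
                                    TRUE, TRUE, TRUE, FALSE),
                        timed_out = FALSE)
  expect_equal(response_accuracy(tbl, "part")$accuracy, 0.5)
  expect_equal(response_accuracy(tbl, "color")$accuracy, 0.75)
  # option counts imply 4AFC / 5AFC chance levels
  expect_equal(1 / 4, 0.25)
  expect_equal(1 / 5, 0.2)
})

test_that("one-sample t matches stats::t.test on a 5-value worked example", {
  x <- c(0.12, 0.05, 0.2, -0.02, 0.09)
  mine <- t_one_sample(x)
  oracle <- t.test(x, mu = 0)
  expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, oracle$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(oracle$parameter))
  # hand formula
  expect_equal(mine$statistic, mean(x) / (sd(x) / sqrt(5)), tolerance = 1e-12)
  # degenerate constant scores flagged, symmetric scores give t ~ 0
  expect_true(t_one_sample(rep(0.3, 4))$degenerate)
  expect_equal(t_one_sample(c(-1, 1, -2, 2))$statistic, 0)
  expect_error(t_one_sample(1), "two observations")
})

test_that("bias score test family covers overall, per-type, and paired terms", {
  set.seed(8)
  scores <- tidyr::crossing(subject_id = sprintf("s%d", 1:20),
                            feature_type = c("shared_trained", "unique_trained")) %>%
    dplyr::mutate(score = rnorm(dplyr::n(), 0.15, 0.05) +
                    ifelse(feature_type == "shared_trained", 0.1, 0))
  tests <- bias_score_tests(scores, fdr = TRUE)
  expect_setequal(tests$term, c("overall_vs_0", "shared_trained_vs_0",
                                "unique_trained_vs_0", "shared_minus_unique"))
  expect_true(all(tests$p.adjusted >= tests$p.value))
  paired <- tests[tests$term == "shared_minus_unique", ]
  expect_gt(paired$statistic, 0)
  expect_equal(paired$df, 19)
})

test_that("BH adjustment matches the manual step-up definition", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # manual step-up oracle: sort ascending, p_(i) * m / i, cumulative min from
  # the largest rank down, restored to input order
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(stepped)))
  oracle <- pmin(1, adj_sorted[order(ord)])
  expect_equal(adjust_fdr(p), oracle, tolerance = 1e-12)
})

test_that("power analysis reproduces the printed sample size and bounds", {
  expect_equal(required_sample_size(0.24, power = 0.80, alpha = 0.05, tails = 1),
               109L)
  # monotone decreasing in effect size; doubling d roughly quarters n
  n_small <- required_sample_size(0.24, 0.8)
  n_big <- required_sample_size(0.48, 0.8)
  expect_lt(n_big, n_small)
  expect_lt(abs(n_big - n_small / 4) / n_small, 0.15)
  # normal-approximation oracle lower-bounds the answer within +3
  za <- qnorm(0.95); zb <- qnorm(0.80)
  approx_n <- ((za + zb) / 0.24)^2
  expect_gte(109, ceiling(approx_n))
  expect_lte(109 - approx_n, 3)
  # independent noncentral-t oracle
  pw <- stats::power.t.test(delta = 0.24, sd = 1, sig.level = 0.05,
                            power = 0.80, type = "one.sample",
                            alternative = "one.sided")
  expect_equal(ceiling(pw$n), 109)
  expect_error(required_sample_size(0, 0.8), "d")
})
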