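test_that("pattern encoding uses 26 units with 6 active per satellite", {
  pats <- fix_patterns
  expect_equal(ncol(pats$patterns), 26L)
  expect_equal(nrow(pats$patterns), 8L)
  expect_true(all(rowSums(pats$patterns) == 6L))
  tab <- table(pats$units$unit_type)
  expect_equal(as.integer(tab[c("class", "code", "part")]), c(2L, 8L, 16L))
  # the two categories occupy disjoint unit subsets
  alpha_units <- pats$units$unit[pats$units$category == "Alpha"]
  alpha_sats <- rownames(pats$patterns)[rowSums(pats$patterns[, alpha_units]) > 0]
  gamma_units <- pats$units$unit[pats$units$category == "Gamma"]
  expect_true(all(rowSums(pats$patterns[alpha_sats, gamma_units]) == 0))
})

test_that("initialization: fixed fan-in masks, weight range, determinism", {
  cfg <- tiny_config()
  net <- init_network(cfg, seed = 31)
  expect_true(all(rowSums(net$M$ec_dg) == round(0.25 * 26)))
  expect_true(all(rowSums(net$M$ec_ca3) == round(0.25 * 26)))
  expect_true(all(rowSums(net$M$dg_ca3) == max(1, round(0.05 * cfg$n_dg))))
  w <- net$W$ec_ca1
  expect_true(all(w >= 0.25 & w <= 0.75))
  expect_identical(init_network(cfg, seed = 31)$W, net$W)
  expect_error(network_config(frac_ec_dg = 0), "fractions")
  expect_error(lesion_config(msp = TRUE, tsp = TRUE), "both")
})

test_that("lesions zero and freeze the right projections", {
  cfg <- tiny_config()
  msp_les <- init_network(cfg, lesion_config(msp = TRUE), seed = 32)
  expect_true(all(msp_les$W$ec_ca1 == 0))
  expect_true(any(msp_les$W$ec_dg > 0))
  tsp_les <- init_network(cfg, lesion_config(tsp = TRUE), seed = 32)
  for (nm in c("ec_dg", "ec_ca3", "dg_ca3", "ca3_ca1")) {
    expect_true(all(tsp_les$W[[nm]] == 0))
  }
  # lesioned projections stay zero through learning
  pat <- fix_patterns$patterns[1, ]
  after <- chl_trial(msp_les, pat)
  expect_true(all(after$W$ec_ca1 == 0))
})

test_that("settling honours clamps, bounds, and inhibition", {
  net <- init_network(tiny_config(), seed = 33)
  pat <- fix_patterns$patterns[2, ]
  out <- settle(net, pat, output_clamp = pat)
  expect_equal(out$ec_out, unname(pat))
  free <- settle(net, pat)
  for (lay in free) expect_true(all(lay >= 0 & lay <= 1))
  expect_lte(sum(free$dg > 0.5), net$config$k_dg)
  expect_lte(sum(free$ca3 > 0.5), net$config$k_ca3)
  expect_lte(sum(free$ca1 > 0.5), net$config$k_ca1)
  expect_error(settle(net, pat, n_cycles = 0), "n_cycles")
})

test_that("zero weights and no clamp give the transfer function's zero-drive output", {
  net <- init_network(tiny_config(), seed = 34)
  for (nm in names(net$W)) net$W[[nm]][] <- 0
  out <- settle(net, rep(0, 26))
  cfg <- net$config
  f0 <- function(gain) plogis(gain * (0 - cfg$theta_hidden))
  expect_equal(out$dg, rep(f0(cfg$gain_hidden), cfg$n_dg), tolerance = 1e-6)
  expect_equal(out$ca3, rep(f0(cfg$gain_hidden), cfg$n_ca3), tolerance = 1e-6)
  expect_equal(out$ca1, rep(f0(cfg$gain_ca1), cfg$n_ca1), tolerance = 1e-6)
})

test_that("CHL update rule: fixed point, sign, and soft bounds", {
  W <- matrix(0.5, 3, 2)
  M <- matrix(1, 3, 2)
  pre <- c(1, 0)
  post <- c(1, 0.5, 0)
  # equal plus and minus coproducts leave weights unchanged
  expect_identical(catwarp:::chl_update(W, M, pre, post, pre, post, lr = 0.2), W)
  # sign of the change matches the sign of the coproduct difference
  up <- catwarp:::chl_update(W, M, pre, post, pre * 0, post * 0, lr = 0.2)
  expect_true(all((up - W)[outer(post, pre) > 0] > 0))
  down <- catwarp:::chl_update(W, M, pre * 0, post * 0, pre, post, lr = 0.2)
  expect_true(all((down - W)[outer(post, pre) > 0] < 0))
  # masked connections never move
  M0 <- M; M0[1, 1] <- 0
  up0 <- catwarp:::chl_update(W, M0, pre, post, pre * 0, post * 0, lr = 0.2)
  expect_equal(up0[1, 1], 0.5)
  # repeated updates stay inside [0, 1]
  Wb <- W
  for (i in 1:200) Wb <- catwarp:::chl_update(Wb, M, pre, post, pre * 0, post * 0, 0.5)
  expect_true(all(Wb >= 0 & Wb <= 1))
})

test_that("pathway minus phases only touch their own projections", {
  net <- init_network(tiny_config(k_hebb_msp = 0, k_hebb_tsp = 0), seed = 35)
  pat <- fix_patterns$patterns[3, ]
  after <- chl_trial(net, pat)
  expect_named(after$phases, c("plus", "minus_tsp", "minus_msp"))
  # recompute the TSP update using only plus and minus_tsp: must reproduce
  p <- after$phases$plus
  m <- after$phases$minus_tsp
  expected <- catwarp:::chl_update(net$W$ec_dg, net$M$ec_dg, p$ec_in, p$dg,
                                   m$ec_in, m$dg, net$config$lr_tsp)
  expect_equal(after$W$ec_dg, expected)
  # and the MSP update only from minus_msp
  mm <- after$phases$minus_msp
  expected_msp <- catwarp:::chl_update(net$W$ec_ca1, net$M$ec_ca1, p$ec_in,
                                       p$ca1, mm$ec_in, mm$ca1,
                                       net$config$lr_msp)
  expect_equal(after$W$ec_ca1, expected_msp)
})

test_that("reconstruction scoring matches its arithmetic definition", {
  pat <- c(rep(1, 6), rep(0, 20))
  expect_equal(reconstruction_score(rep(0.9, 26), pat), 1)
  expect_equal(reconstruction_score(rep(0, 26), pat), 0)
  half <- c(rep(0.9, 3), rep(0.1, 3), rep(0, 20))
  expect_equal(reconstruction_score(half, pat), 0.5)
  expect_equal(reconstruction_score(rep(0.9, 26), pat, all_units = TRUE), 6 / 26)
})

test_that("training runs 16 trials per epoch with every pattern twice", {
  net <- init_network(tiny_config(), seed = 36)
  net <- train_network(net, fix_patterns, n_epochs = 2, seed = 37)
  expect_equal(net$log$epoch, 0:2)
  expect_true(all(vapply(net$trial_orders, length, integer(1)) == 16L))
  for (ord in net$trial_orders) expect_true(all(table(ord) == 2L))
  # deterministic
  net2 <- train_network(init_network(tiny_config(), seed = 36), fix_patterns,
                        n_epochs = 2, seed = 37)
  expect_identical(net$W, net2$W)
})

test_that("training improves reconstruction over the untrained network", {
  # Monte-Carlo over 10 initializations at the shipped defaults
  deltas <- vapply(1:10, function(s) {
    net <- train_network(init_network(seed = s), fix_patterns, 6, seed = s + 100)
    diff(net$log$accuracy[c(1, 7)])
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("the monosynaptic three-layer autoencoder converges under CHL", {
  # MSP-only model is a 26 -> CA1 -> 26 autoencoder; training shrinks the
  # plus/minus output disagreement and lifts reconstruction accuracy.
  net0 <- init_network(lesions = lesion_config(tsp = TRUE), seed = 38)
  pm_gap <- function(net) {
    mean(vapply(1:8, function(i) {
      pat <- fix_patterns$patterns[i, ]
      minus <- settle(net, pat, pathway = "msp_only")
      mean(abs(minus$ec_out - pat))
    }, numeric(1)))
  }
  net <- train_network(net0, fix_patterns, 6, seed = 39)
  expect_lt(pm_gap(net), pm_gap(net0))
  expect_gt(net$log$accuracy[7], net$log$accuracy[1])
})

test_that("feature probes return bounded, reproducible CA1 initial responses", {
  net <- train_network(init_network(tiny_config(), seed = 40), fix_patterns,
                       n_epochs = 1, seed = 41)
  v <- probe_feature(net, 5)
  expect_length(v, net$config$n_ca1)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(probe_feature(net, 5), v)
  P <- probe_features(net)
  expect_equal(dim(P), c(26L, net$config$n_ca1))
  expect_equal(P[5, ], v)
})

test_that("DG separates same-category patterns more than CA1", {
  res <- vapply(1:10, function(s) {
    net <- train_network(init_network(seed = s), fix_patterns, 6, seed = s + 100)
    reps <- lapply(1:8, function(i) settle(net, fix_patterns$patterns[i, ],
                                           bigloop = FALSE))
    sim <- function(lay) {
      M <- t(vapply(reps, function(x) x[[lay]], numeric(length(reps[[1]][[lay]]))))
      r1 <- cor(t(M[1:4, ]))
      r2 <- cor(t(M[5:8, ]))
      mean(c(r1[lower.tri(r1)], r2[lower.tri(r2)]))
    }
    sim("dg") - sim("ca1")
  }, numeric(1))
  expect_lt(mean(res), 0)
})

test_that("cohorts are reproducible from the master seed", {
  pats <- fix_patterns
  c1 <- run_cohort(pats, tiny_config(), conditions = "intact", n_inits = 2,
                   master_seed = 7, n_epochs = 1)
  c2 <- run_cohort(pats, tiny_config(), conditions = "intact", n_inits = 2,
                   master_seed = 7, n_epochs = 1)
  expect_identical(c1$accuracy, c2$accuracy)
  expect_identical(c1$probes, c2$probes)
  expect_equal(dplyr::n_distinct(c1$accuracy$init), 2L)
})
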