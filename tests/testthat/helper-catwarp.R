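# Shared fixtures, built in code. The "tiny" network config keeps structural
# tests fast; science-level assertions use the shipped defaults.

fix_set <- satellite_set(seed = 11)
fix_assignment <- assign_colors(fix_set, arrangement_id = 1, seed = 12)
fix_patterns <- build_patterns(fix_set)

tiny_config <- function(...) {
  args <- list(n_dg = 60L, n_ca3 = 20L, n_ca1 = 30L, n_cycles = 30L)
  over <- list(...)
  args[names(over)] <- over
  do.call(network_config, args)
}

expect_no_violations <- function(trials) {
  v <- validate_schedule(trials)
  expect_identical(attr(v, "n_violations"), 0L)
}
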