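# End-to-end reproducible runs: configuration, master-seed derivation,
# artifact writing. Every stochastic stage derives its seed deterministically
# from the master seed and stage name, so a rerun with the same config yields
# an identical manifest hash.

#' Configuration for the model experiment
#'
#' @param master_seed Master seed; all stage seeds derive from it.
#' @param n_inits Initializations per condition.
#' @param conditions Lesion conditions to train.
#' @param n_epochs Training epochs.
#' @param network A `chorse_config`.
#' @param rsa_features `"all"` or `"parts"` (feature set entering RSA/MDS).
#' @return List of class `catwarp_model_config`.
#' @export
model_experiment_config <- function(master_seed = 1L, n_inits = 50L,
                                    conditions = c("intact", "msp_only", "tsp_only"),
                                    n_epochs = 6L,
                                    network = network_config(),
                                    rsa_features = "all") {
  structure(list(master_seed = master_seed, n_inits = n_inits,
                 conditions = conditions, n_epochs = n_epochs,
                 network = network, rsa_features = rsa_features),
            class = "catwarp_model_config")
}

#' Run the full model experiment
#'
#' Stimulus design, 26-unit pattern construction, cohort training across the
#' configured lesion conditions, feature-level RSA, the shared-vs-unique
#' pathway contrast, and MDS of the lesioned conditions' CA1 similarity
#' structure. Optionally writes CSV artifacts and a JSON manifest.
#'
#' @param config A `catwarp_model_config`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `catwarp_model_experiment`: `set`, `patterns`,
#'   `cohort`, `rsa`, `role_means`, `contrast`, `mds`, `config`, `manifest`.
#' @export
run_model_experiment <- function(config = model_experiment_config(),
                                 out_dir = NULL) {
  ms <- config$master_seed
  set <- satellite_set(derive_seed(ms, "stimuli"))
  patterns <- build_patterns(set)
  cohort <- run_cohort(patterns, config$network, config$conditions,
                       config$n_inits, master_seed = ms,
                       n_epochs = config$n_epochs)
  rsa <- cohort_rsa(cohort, config$rsa_features)
  role_means <- rsa_role_means(rsa)
  lesioned <- intersect(config$conditions, c("msp_only", "tsp_only"))
  contrast <- if (length(lesioned) == 2L)
    shared_vs_unique_contrast(role_means, lesioned) else NULL
  mds <- lapply(setNames(lesioned, lesioned), function(cond) {
    mds_embed(cohort_similarity(cohort, cond, config$rsa_features))
  })
  manifest <- list(
    master_seed = ms,
    config_hash = rlang::hash(config),
    n_inits = config$n_inits,
    conditions = config$conditions,
    stage_seeds = list(stimuli = derive_seed(ms, "stimuli")))
  manifest$hash <- rlang::hash(manifest)
  bundle <- structure(list(set = set, patterns = patterns, cohort = cohort,
                           rsa = rsa, role_means = role_means,
                           contrast = contrast, mds = mds, config = config,
                           manifest = manifest),
                      class = "catwarp_model_experiment")
  if (!is.null(out_dir)) write_model_artifacts(bundle, out_dir)
  bundle
}

write_model_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(bundle$cohort$accuracy, "model_accuracy.csv")
  wr(bundle$rsa, "feature_rsa_z.csv")
  wr(bundle$role_means, "rsa_role_means.csv")
  if (!is.null(bundle$contrast)) {
    wr(bundle$contrast$t_tests, "contrast_t_tests.csv")
    wr(bundle$contrast$anova, "contrast_anova.csv")
  }
  for (cond in names(bundle$mds)) {
    wr(bundle$mds[[cond]]$coords, paste0("mds_", cond, ".csv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Configuration for the behavioral experiment
#'
#' @param master_seed Master seed.
#' @param n_subjects_exp1,n_subjects_exp2 Cohort sizes for the two variants
#'   (defaults 85 and 109, the experiments' post-exclusion sample sizes).
#' @param params A `participant_params` for the synthetic cohorts.
#' @param arrangement_id Color arrangement (1 or 2).
#' @return List of class `catwarp_behavior_config`.
#' @export
behavior_experiment_config <- function(master_seed = 1L,
                                       n_subjects_exp1 = 85L,
                                       n_subjects_exp2 = 109L,
                                       params = participant_params(),
                                       arrangement_id = 1L) {
  structure(list(master_seed = master_seed,
                 n_subjects_exp1 = n_subjects_exp1,
                 n_subjects_exp2 = n_subjects_exp2,
                 params = params, arrangement_id = arrangement_id),
            class = "catwarp_behavior_config")
}

#' Run the full behavioral experiment pipeline
#'
#' Design, constraint-checked schedules for both experiment variants,
#' synthetic cohorts, and the bias/accuracy/profile/test analyses, for the
#' learning phase of both variants and the post-learning test of the second.
#'
#' @param config A `catwarp_behavior_config`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `catwarp_behavior_experiment`.
#' @export
run_behavior_experiment <- function(config = behavior_experiment_config(),
                                    out_dir = NULL) {
  ms <- config$master_seed
  set <- satellite_set(derive_seed(ms, "stimuli"))
  assignment <- assign_colors(set, config$arrangement_id,
                              derive_seed(ms, "colors"))
  novel <- build_novel_set(set, derive_seed(ms, "novel"))

  sched1 <- bind_rows(
    build_exposure(set, assignment, "exp1", derive_seed(ms, "exposure1")),
    build_learning_phase(set, assignment, derive_seed(ms, "learning1")))
  sched2 <- bind_rows(
    build_exposure(set, assignment, "exp2", derive_seed(ms, "exposure2")),
    build_learning_phase(set, assignment, derive_seed(ms, "learning2"),
                         exp2_decoupling = TRUE),
    build_post_test(set, novel, assignment, derive_seed(ms, "posttest")))
  v1 <- validate_schedule(sched1)
  v2 <- validate_schedule(sched2)

  resp1 <- simulate_cohort(sched1, assignment, config$params,
                           config$n_subjects_exp1, derive_seed(ms, "cohort1"))
  resp2 <- simulate_cohort(sched2, assignment, config$params,
                           config$n_subjects_exp2, derive_seed(ms, "cohort2"))

  analyze <- function(resp, phase_name) {
    sub <- resp %>% filter(.data$phase == phase_name)
    list(
      bias = attraction_bias(sub, .data$subject_id, .data$feature_type),
      bias_blocks = attraction_bias(sub, .data$subject_id, .data$feature_type,
                                    .data$block),
      profile = choice_profile(sub, .data$subject_id, .data$feature_type),
      part_accuracy = response_accuracy(sub, "part", .data$subject_id,
                                        .data$feature_type, .data$block),
      tests = bias_score_tests(
        attraction_bias(sub, .data$subject_id, .data$feature_type)))
  }
  results <- list(exp1 = analyze(resp1, "learning"),
                  exp2 = analyze(resp2, "learning"),
                  post_test = analyze(resp2, "post_test"))

  manifest <- list(master_seed = ms, config_hash = rlang::hash(config),
                   n_violations = attr(v1, "n_violations") + attr(v2, "n_violations"))
  manifest$hash <- rlang::hash(manifest)
  bundle <- structure(list(set = set, assignment = assignment, novel = novel,
                           schedules = list(exp1 = sched1, exp2 = sched2),
                           validation = list(exp1 = v1, exp2 = v2),
                           responses = list(exp1 = resp1, exp2 = resp2),
                           results = results, config = config,
                           manifest = manifest),
                      class = "catwarp_behavior_experiment")
  if (!is.null(out_dir)) write_behavior_artifacts(bundle, out_dir)
  bundle
}

write_behavior_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) write.csv(x, file.path(out_dir, f), row.names = FALSE)
  for (v in names(bundle$schedules)) wr(bundle$schedules[[v]],
                                        paste0("schedule_", v, ".csv"))
  for (v in names(bundle$responses)) wr(bundle$responses[[v]],
                                        paste0("responses_", v, ".csv"))
  for (v in names(bundle$results)) {
    wr(bundle$results[[v]]$bias_blocks, paste0("bias_blocks_", v, ".csv"))
    wr(bundle$results[[v]]$profile, paste0("choice_profile_", v, ".csv"))
    wr(bundle$results[[v]]$tests, paste0("bias_tests_", v, ".csv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
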