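#' Pipeline run configuration
#'
#' A single nested configuration for end-to-end runs, with every stage
#' parameter defaulting to the analysis value used throughout the package
#' (15 Hz cutoff, 30 Hz analysis rate, 50-trial inclusion, 100 ms AR
#' windows with one-sample steps, 10000 bootstrap reps, one-tailed
#' Bonferroni over 6 age tests). Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param cohort a [cohort_config()].
#' @param truth named list of arguments for [ground_truth_dynamics()]
#'   (`n_sensors` is filled from the cohort config).
#' @param analysis named list of [analyze_cohort()] parameters, including
#'   `lock_windows`.
#' @param inference named list with `reps`, `alpha`, `n_tests`, `tail`,
#'   `method`.
#' @param seed integer seed for the whole run.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       truth = list(),
                       analysis = list(),
                       inference = list(),
                       seed = 1) {
  analysis_def <- list(locks = c("cue", "stimulus", "response"),
                       pca_locks = c("stimulus", "response"),
                       lock_windows = lock_windows(),
                       target_fs = 30, cutoff = 15, filter_order = 4,
                       min_trials = 50, window_ms = 100,
                       step_samples = 1, min_pairs = 4)
  inference_def <- list(reps = 10000, alpha = 0.05, n_tests = 6,
                        tail = "negative", method = "bootstrap")
  structure(
    list(cohort = cohort, truth = truth,
         analysis = utils::modifyList(analysis_def, analysis),
         inference = utils::modifyList(inference_def, inference),
         seed = as.integer(seed)),
    class = "run_config")
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop_invalid("not a run_config")
  a <- config$analysis
  if (is.null(a$lock_windows) || !all(a$locks %in% names(a$lock_windows)))
    stop_invalid("config is missing lock windows for the requested locks")
  for (lk in a$locks)
    if (a$lock_windows[[lk]][1] >= a$lock_windows[[lk]][2])
      stop_invalid(sprintf("lock window for %s must have start < end", lk))
  if (!inherits(config$cohort, "cohort_config"))
    stop_invalid("config$cohort must be a cohort_config")
  if (config$inference$reps < 100) stop_invalid("inference reps must be >= 100")
  invisible(config)
}

#' Run the full synthetic-cohort pipeline from a configuration
#'
#' Validates the configuration, simulates the cohort, runs the analysis
#' stages and the cluster-corrected age tests, and assembles a manifest
#' (package version, seed, parameters, content hashes of the result
#' tables) so every artifact is regenerable from config + seed alone. With
#' `out_dir` set, tidy results are written as CSV and the manifest as
#' JSON.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return an `eeg_pipeline_run` list: `dynamics` (the `cohort_dynamics`),
#'   `age_tests`, `manifest`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_run_config(config)
  cc <- config$cohort
  cc$seed <- sub_seed(config$seed, 1L)
  truth <- do.call(ground_truth_dynamics,
                   utils::modifyList(list(n_sensors = cc$n_sensors),
                                     config$truth))
  cohort <- simulate_cohort(cc, truth, locks = config$analysis$locks)
  a <- config$analysis
  dyn <- analyze_cohort(cohort, locks = a$locks, pca_locks = a$pca_locks,
                        target_fs = a$target_fs, cutoff = a$cutoff,
                        filter_order = a$filter_order,
                        min_trials = a$min_trials, window_ms = a$window_ms,
                        step_samples = a$step_samples,
                        min_pairs = a$min_pairs)
  inf <- config$inference
  tests <- age_effect_tests(dyn$eigs, locks = a$locks, tail = inf$tail,
                            reps = inf$reps, alpha = inf$alpha,
                            n_tests = inf$n_tests,
                            seed = sub_seed(config$seed, 2L),
                            method = inf$method)
  manifest <- list(
    package = "eegdynamics",
    version = as.character(utils::packageVersion("eegdynamics")),
    seed = config$seed,
    parameters = list(cohort = unclass(cc), analysis = a, inference = inf,
                      truth = config$truth),
    n_recordings = nrow(cohort),
    hashes = list(eigs = rlang::hash(dyn$eigs),
                  behavior = rlang::hash(dyn$behavior),
                  age_tests = rlang::hash(tests)))
  run <- structure(list(dynamics = dyn, age_tests = tests,
                        manifest = manifest, config = config),
                   class = "eeg_pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @exportS3Method print eeg_pipeline_run
print.eeg_pipeline_run <- function(x, ...) {
  cat(sprintf("<eeg_pipeline_run> seed %d, %d recordings\n",
              x$manifest$seed, x$manifest$n_recordings))
  print(x$age_tests)
  invisible(x)
}

#' Write tidy pipeline outputs to disk
#'
#' Eigenvalue time courses, behavior summaries and test summaries as CSV;
#' the manifest as JSON.
#'
#' @param run an `eeg_pipeline_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$dynamics$eigs, file.path(out_dir, "eigenvalues.csv"),
                   row.names = FALSE)
  utils::write.csv(run$dynamics$behavior, file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(run$age_tests, file.path(out_dir, "age_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(cohort = unclass(config$cohort), truth = config$truth,
            analysis = config$analysis, inference = config$inference,
            seed = config$seed)
  x$cohort$condition_probs <- as.numeric(x$cohort$condition_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(cohort = do.call(cohort_config, x$cohort),
             truth = x$truth,
             analysis = x$analysis,
             inference = x$inference,
             seed = x$seed)
}
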