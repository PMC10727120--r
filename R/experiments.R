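#' Repeated synthetic-cohort experiments on the age effect
#'
#' Repeatedly simulates a reduced longitudinal cohort at the analysis rate,
#' runs the full pipeline (segmentation, inclusion, PCA, z-scoring,
#' residuals, AR(1) sweep) and the cluster-corrected age-test family, and
#' records which cells rejected. With `age_slope = 0` this measures the
#' family-wise type-I error of the whole pipeline; with a negative slope in
#' the stimulus/response epochs it measures power and epoch specificity
#' (the cue epoch carries no injected effect, so cue rejections are false
#' positives by construction).
#'
#' @param n_runs number of independent pipeline runs.
#' @param n_subjects,n_trials,n_sensors reduced cohort dimensions.
#' @param age_slope eigenvalue change per year of age applied to both
#'   eigenvalues in the stimulus- and response-locked epochs (the cue epoch
#'   stays flat); 0 gives a null cohort.
#' @param missingness probability of skipping a wave.
#' @param reps bootstrap replicates per test.
#' @param locks locks to simulate and test.
#' @param seed master seed; each run receives an independent substream.
#' @param truth_args extra overrides for [ground_truth_dynamics()].
#' @return tibble with one row per run and test cell: `run`, `lock`,
#'   `eigenvalue`, `any_sig`, `min_p`, `n_sig_windows`.
#' @export
run_age_experiment <- function(n_runs, n_subjects = 40, n_trials = 64,
                               n_sensors = 16, age_slope = 0,
                               missingness = 0.24, reps = 500,
                               locks = c("cue", "stimulus", "response"),
                               seed = 1, truth_args = list()) {
  rows <- purrr::map(seq_len(n_runs), function(r) {
    cc <- cohort_config(n_subjects = n_subjects, n_trials = n_trials,
                        n_sensors = n_sensors, fs_raw = 30,
                        missingness = missingness,
                        seed = sub_seed(seed, r, 1L))
    truth <- do.call(ground_truth_dynamics, utils::modifyList(
      list(n_sensors = n_sensors,
           age_slopes = list(cue = c(0, 0),
                             stimulus = rep(age_slope, 2),
                             response = rep(age_slope, 2))),
      truth_args))
    cohort <- simulate_cohort(cc, truth, locks = locks)
    # the 50-trial rule scaled to reduced desk-scale sessions
    dyn <- analyze_cohort(cohort, locks = locks,
                          pca_locks = intersect(c("stimulus", "response"), locks),
                          min_trials = min(50, floor(0.8 * n_trials)))
    tests <- age_effect_tests(dyn$eigs, locks = locks, reps = reps,
                              n_tests = 6, seed = sub_seed(seed, r, 2L))
    dplyr::mutate(tests, run = r, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Latency-jitter control analysis
#'
#' Generates control cohorts in which each single trial is the
#' condition-mean ERP shifted by a trial-specific latency offset (SD set
#' per age group, defaulting to the age groups' reaction-time SDs of
#' 97/76/72 ms) plus white noise — no true dynamics gradient exists — and
#' pushes them through the identical residual/AR(1)/inference pipeline.
#' Optionally runs a matched dynamics-generated cohort for contrast: age
#' effects that survive in the dynamics cohort but not in the jittered one
#' cannot be explained by ERP-timing variability alone.
#'
#' @param n_subjects,n_trials cohort dimensions (jittered sessions are
#'   matched in trials and subjects).
#' @param truth a [ground_truth_dynamics()] supplying the mean ERPs (and,
#'   for the comparison cohort, the true age-graded dynamics).
#' @param jitter a [jitter_config()].
#' @param waves target ages; each wave's jitter SD is looked up by target
#'   age.
#' @param missingness probability of skipping a wave.
#' @param locks locks to generate and test.
#' @param reps bootstrap replicates.
#' @param seed master seed.
#' @param compare also run a matched dynamics-generated cohort.
#' @return a `jitter_control` list: `jitter_tests` (age-test summary on the
#'   jittered cohort), `jitter_eigs`, and when `compare` is TRUE
#'   `dynamics_tests` for the contrast.
#' @export
run_jitter_control <- function(n_subjects = 40, n_trials = 64,
                               truth = ground_truth_dynamics(n_sensors = 16),
                               jitter = jitter_config(),
                               waves = c(12, 15, 18), missingness = 0.24,
                               locks = c("cue", "stimulus", "response"),
                               reps = 500, seed = 1, compare = FALSE) {
  erps <- lapply(setNames(locks, locks), function(lk)
    mean_erps_from_truth(truth, lk))
  eig_rows <- list()
  for (i in seq_len(n_subjects)) {
    set.seed(sub_seed(seed, i, 0L))
    attended <- runif(length(waves)) >= missingness
    ages <- waves + rnorm(length(waves), 0, 0.5)
    for (w in seq_along(waves)) {
      if (!attended[w]) next
      set.seed(sub_seed(seed, i, w))
      rid <- sprintf("J%04d_w%d", i, w)
      rec <- list(recording_id = rid, participant = sprintf("P%04d", i),
                  age = ages[w], sex = NA_character_, wave = w)
      lats <- lapply(setNames(locks, locks), function(lk)
        make_jittered_dataset(erps[[lk]], jitter, n_trials = n_trials,
                              age = waves[w], lock = lk, recording = rec))
      lats <- zscore_latent_list(lats)
      for (lk in locks) {
        dyn <- sweep_dynamics(compute_residuals(lats[[lk]]))
        eig_rows[[length(eig_rows) + 1]] <- dplyr::mutate(
          dyn, recording_id = rid, participant = rec$participant,
          age = ages[w], wave = w, lock = lk, .before = 1)
      }
    }
  }
  jitter_eigs <- dplyr::bind_rows(eig_rows)
  jitter_tests <- age_effect_tests(jitter_eigs, locks = locks, reps = reps,
                                   n_tests = 6, seed = sub_seed(seed, 7L))
  out <- list(jitter_tests = jitter_tests, jitter_eigs = jitter_eigs,
              jitter = jitter, seed = seed)
  if (compare) {
    cc <- cohort_config(n_subjects = n_subjects, n_trials = n_trials,
                        n_sensors = nrow(truth$sensor_loadings), fs_raw = 30,
                        missingness = missingness, seed = sub_seed(seed, 8L))
    cohort <- simulate_cohort(cc, truth, locks = locks)
    dyn <- analyze_cohort(cohort, locks = locks,
                          min_trials = min(50, floor(0.8 * n_trials)))
    out$dynamics_tests <- age_effect_tests(dyn$eigs, locks = locks,
                                           reps = reps, n_tests = 6,
                                           seed = sub_seed(seed, 9L))
  }
  structure(out, class = "jitter_control")
}

#' @exportS3Method print jitter_control
print.jitter_control <- function(x, ...) {
  cat("<jitter_control> age tests on latency-jittered data (no true dynamics):\n")
  print(x$jitter_tests)
  if (!is.null(x$dynamics_tests)) {
    cat("matched dynamics-generated cohort:\n")
    print(x$dynamics_tests)
  }
  invisible(x)
}

# session-wide z-scoring for already-latent trials (pooled across locks)
zscore_latent_list <- function(lats) {
  k <- dim(lats[[1]]$values)[2]
  mu <- vn <- numeric(k)
  ntot <- sum(vapply(lats, function(l) prod(dim(l$values)[c(1, 3)]), 0))
  for (l in lats) for (j in seq_len(k)) mu[j] <- mu[j] + sum(l$values[, j, ])
  mu <- mu / ntot
  for (l in lats) for (j in seq_len(k))
    vn[j] <- vn[j] + sum((l$values[, j, ] - mu[j])^2)
  sdv <- sqrt(vn / ntot)
  if (any(sdv <= 0))
    stop_numerical("flat latent component; cannot z-score")
  lapply(lats, function(l) {
    for (j in seq_len(k)) l$values[, j, ] <- (l$values[, j, ] - mu[j]) / sdv[j]
    l$zscore_params <- list(mean = mu, sd = sdv)
    l
  })
}
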