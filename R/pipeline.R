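#' Run the dynamics analysis over a cohort of epoched recordings
#'
#' Executes the per-recording stages end to end: optional lowpass/
#' downsample (skipped when data are already at the analysis rate),
#' event-locked segmentation, the minimum-trial inclusion rule per lock,
#' the grand-average PCA fit (stimulus- and response-locked conditions
#' only), session-wide projection and z-scoring, condition-mean residuals,
#' and the sliding-window AR(1) eigenvalue sweep.
#'
#' @param cohort an `eeg_cohort` from [simulate_cohort()], or any tibble
#'   with columns `recording_id`, `participant`, `age`, `sex`, `wave` and
#'   an `epochs` list-column of per-lock [eeg_epochs].
#' @param locks locks to analyse.
#' @param pca_locks locks entering the component-space fit.
#' @param target_fs,cutoff,filter_order preprocessing parameters.
#' @param min_trials per-lock inclusion threshold.
#' @param window_ms,step_samples,min_pairs AR(1) sweep parameters.
#' @return a `cohort_dynamics` list: `eigs` (long tibble: recording,
#'   metadata, lock, `window_ms`, `eig1`, `eig2`, `n_pairs`, `complex`),
#'   `behavior` (per-recording summaries), `space` (the fitted
#'   `component_space`), `inclusion` (per-lock counts and inclusion flags)
#'   and `params`.
#' @export
analyze_cohort <- function(cohort,
                           locks = c("cue", "stimulus", "response"),
                           pca_locks = c("stimulus", "response"),
                           target_fs = 30, cutoff = 15, filter_order = 4,
                           min_trials = 50, window_ms = 100,
                           step_samples = 1, min_pairs = 4) {
  stopifnot(is.data.frame(cohort), "epochs" %in% names(cohort))
  segd <- vector("list", nrow(cohort))
  counts <- list()
  for (r in seq_len(nrow(cohort))) {
    eps <- cohort$epochs[[r]]
    out <- list()
    for (lk in intersect(locks, names(eps))) {
      e <- eps[[lk]]
      if (e$fs > target_fs + 1e-9)
        e <- lowpass_downsample(e, cutoff = cutoff, target_fs = target_fs,
                                order = filter_order)
      e <- suppressMessages(segment_epochs(e, lock = lk))
      out[[lk]] <- e
      counts[[length(counts) + 1]] <- list(
        recording_id = cohort$recording_id[r], lock = lk,
        n_trials = dim(e$data)[1])
    }
    segd[[r]] <- out
  }
  counts <- tibble::tibble(
    recording_id = vapply(counts, `[[`, "", "recording_id"),
    lock = vapply(counts, `[[`, "", "lock"),
    n_trials = vapply(counts, `[[`, 0L, "n_trials"))
  inclusion <- apply_inclusion_rule(counts, min_trials = min_trials)
  included <- function(rid, lk)
    any(inclusion$included & inclusion$recording_id == rid & inclusion$lock == lk)

  ga_epochs <- list()
  for (r in seq_len(nrow(cohort)))
    for (lk in intersect(pca_locks, names(segd[[r]])))
      if (included(cohort$recording_id[r], lk))
        ga_epochs[[length(ga_epochs) + 1]] <- segd[[r]][[lk]]
  if (!length(ga_epochs))
    stop_invalid("no recordings pass the inclusion rule for the PCA locks")
  space <- fit_component_space(grand_average_erps(ga_epochs, locks = pca_locks))

  eig_rows <- list()
  trials_rows <- list()
  for (r in seq_len(nrow(cohort))) {
    use_locks <- names(segd[[r]])[vapply(names(segd[[r]]), function(lk)
      included(cohort$recording_id[r], lk), TRUE)]
    if (!length(use_locks)) next
    lat <- project_and_zscore(segd[[r]][use_locks], space)
    for (lk in use_locks) {
      res <- compute_residuals(lat[[lk]])
      dyn <- sweep_dynamics(res, width = window_ms,
                            step_samples = step_samples, min_pairs = min_pairs)
      nw <- nrow(dyn)
      meta <- tibble::new_tibble(list(
        recording_id = rep(cohort$recording_id[r], nw),
        participant = rep(cohort$participant[r], nw),
        age = rep(cohort$age[r], nw), sex = rep(cohort$sex[r], nw),
        wave = rep(cohort$wave[r], nw), lock = rep(lk, nw)), nrow = nw)
      eig_rows[[length(eig_rows) + 1]] <-
        tibble::new_tibble(c(meta, dyn), nrow = nw)
    }
    tr <- segd[[r]][[use_locks[1]]]$trials
    trials_rows[[length(trials_rows) + 1]] <- dplyr::mutate(
      tr, recording_id = cohort$recording_id[r],
      participant = cohort$participant[r], age = cohort$age[r],
      sex = cohort$sex[r], wave = cohort$wave[r])
  }
  eigs <- dplyr::bind_rows(eig_rows)
  behavior <- behavior_tables(dplyr::bind_rows(trials_rows))
  structure(
    list(eigs = eigs, behavior = behavior, space = space,
         inclusion = inclusion,
         params = list(locks = locks, pca_locks = pca_locks,
                       target_fs = target_fs, cutoff = cutoff,
                       filter_order = filter_order, min_trials = min_trials,
                       window_ms = window_ms, step_samples = step_samples,
                       min_pairs = min_pairs)),
    class = "cohort_dynamics")
}

#' @exportS3Method print cohort_dynamics
print.cohort_dynamics <- function(x, ...) {
  cat(sprintf("<cohort_dynamics> %d recordings, locks: %s\n",
              length(unique(x$eigs$recording_id)),
              paste(unique(x$eigs$lock), collapse = ", ")))
  cat(sprintf("  component space explains %s of grand-average variance\n",
              paste(sprintf("%.1f%%", 100 * x$space$explained_fraction),
                    collapse = " + ")))
  invisible(x)
}

#' Cluster-corrected age tests on the eigenvalue time courses
#'
#' Runs the directional test `eigenvalue ~ age + (1 | participant)` with
#' TFCE clustering and the bootstrap family-wise null for every requested
#' lock and eigenvalue (the default family of 2 eigenvalues x 3 locks is
#' Bonferroni-corrected at `alpha / 6`). The hypothesized direction is
#' negative: faster relaxation (smaller eigenvalues) in older adolescents.
#'
#' @param eigs long eigenvalue tibble from [analyze_cohort()]`$eigs`.
#' @param locks,eigenvalues cells of the test family.
#' @param tail hypothesized direction (default `"negative"`).
#' @inheritParams cluster_test
#' @param n_tests family size for Bonferroni correction (defaults to the
#'   number of cells).
#' @param keep_tests keep the full `eeg_cluster_test` objects in a
#'   list-column.
#' @return tibble with one row per cell: `lock`, `eigenvalue`,
#'   `n_sig_windows`, `min_p`, `any_sig` (plus `test` when requested).
#' @export
age_effect_tests <- function(eigs, locks = c("cue", "stimulus", "response"),
                             eigenvalues = c("eig1", "eig2"),
                             tail = "negative", reps = 10000, alpha = 0.05,
                             n_tests = length(locks) * length(eigenvalues),
                             seed = NULL, method = "bootstrap",
                             keep_tests = FALSE) {
  cells <- tidyr::expand_grid(lock = locks, eigenvalue = eigenvalues)
  rows <- purrr::pmap(cells, function(lock, eigenvalue) {
    d <- dplyr::filter(eigs, .data$lock == !!lock)
    ct <- cluster_test(d, outcome = eigenvalue, predictor = "age",
                       tail = tail, reps = reps, alpha = alpha,
                       n_tests = n_tests,
                       seed = if (is.null(seed)) NULL else
                         sub_seed(seed, match(lock, locks),
                                  match(eigenvalue, eigenvalues)),
                       method = method)
    out <- tibble::tibble(lock = lock, eigenvalue = eigenvalue,
                          n_sig_windows = sum(ct$windows$sig, na.rm = TRUE),
                          min_p = min(ct$windows$p),
                          any_sig = any(ct$windows$sig, na.rm = TRUE))
    if (keep_tests) out$test <- list(ct)
    out
  })
  dplyr::bind_rows(rows)
}

#' Cluster-corrected behavior tests on the eigenvalue time courses
#'
#' Tests `behavior ~ eigenvalue + (1 | participant)` per window for each
#' behavioral outcome, lock and eigenvalue. Default directions follow the
#' attractor hypothesis: larger eigenvalues (slower relaxation) predict
#' slower, more variable, less accurate responding, so RT and RT SD are
#' tested with a positive tail and accuracy with a negative tail. The
#' default family (3 behaviors x 3 locks x 2 eigenvalues = 18) is
#' Bonferroni-corrected at `alpha / 18`.
#'
#' @inheritParams age_effect_tests
#' @param behavior per-recording behavior tibble from
#'   [analyze_cohort()]`$behavior`.
#' @param outcomes behavioral outcomes to test.
#' @param tails named vector of test directions per outcome.
#' @export
behavior_effect_tests <- function(eigs, behavior,
                                  locks = c("cue", "stimulus", "response"),
                                  eigenvalues = c("eig1", "eig2"),
                                  outcomes = c("rt_mean", "rt_sd", "accuracy"),
                                  tails = c(rt_mean = "positive",
                                            rt_sd = "positive",
                                            accuracy = "negative"),
                                  reps = 10000, alpha = 0.05, n_tests = 18,
                                  seed = NULL, method = "bootstrap",
                                  keep_tests = FALSE) {
  d_all <- dplyr::left_join(
    eigs, dplyr::select(behavior, "recording_id", dplyr::all_of(outcomes)),
    by = "recording_id")
  cells <- tidyr::expand_grid(outcome = outcomes, lock = locks,
                              eigenvalue = eigenvalues)
  rows <- purrr::pmap(cells, function(outcome, lock, eigenvalue) {
    d <- dplyr::filter(d_all, .data$lock == !!lock)
    ct <- cluster_test(d, outcome = outcome, predictor = eigenvalue,
                       tail = tails[[outcome]], reps = reps, alpha = alpha,
                       n_tests = n_tests,
                       seed = if (is.null(seed)) NULL else
                         sub_seed(seed, match(outcome, outcomes),
                                  match(lock, locks),
                                  match(eigenvalue, eigenvalues)),
                       method = method)
    out <- tibble::tibble(outcome = outcome, lock = lock,
                          eigenvalue = eigenvalue,
                          n_sig_windows = sum(ct$windows$sig, na.rm = TRUE),
                          min_p = min(ct$windows$p),
                          any_sig = any(ct$windows$sig, na.rm = TRUE))
    if (keep_tests) out$test <- list(ct)
    out
  })
  dplyr::bind_rows(rows)
}
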