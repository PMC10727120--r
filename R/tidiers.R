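#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster test into its per-window table
#'
#' @param x an `eeg_cluster_test`.
#' @param ... unused.
#' @return tibble with `window_ms`, `t`, `tfce`, `p`, `sig`.
#' @export
tidy.eeg_cluster_test <- function(x, ...) x$windows

#' One-row summary of a cluster test
#'
#' @param x an `eeg_cluster_test`.
#' @param ... unused.
#' @return tibble with the test specification and its outcome: number of
#'   significant windows and clusters, minimum corrected p-value, the null
#'   quantile at the corrected alpha.
#' @export
glance.eeg_cluster_test <- function(x, ...) {
  s <- x$spec
  tibble::tibble(
    outcome = s$outcome, predictor = s$predictor, tail = s$tail,
    method = s$method, reps = s$reps,
    alpha_corrected = s$alpha_corrected,
    n_windows = nrow(x$windows),
    n_sig_windows = sum(x$windows$sig, na.rm = TRUE),
    n_clusters = nrow(x$clusters),
    min_p = min(x$windows$p),
    null_crit = as.numeric(stats::quantile(x$null_max, 1 - s$alpha_corrected)),
    n_recordings = s$n_recordings, n_participants = s$n_participants)
}

#' Tidy a cohort analysis into its long eigenvalue table
#'
#' @param x a `cohort_dynamics`.
#' @param ... unused.
#' @export
tidy.cohort_dynamics <- function(x, ...) x$eigs

#' One-row summary of a cohort analysis
#'
#' @param x a `cohort_dynamics`.
#' @param ... unused.
#' @export
glance.cohort_dynamics <- function(x, ...) {
  tibble::tibble(
    n_recordings = length(unique(x$eigs$recording_id)),
    n_participants = length(unique(x$eigs$participant)),
    n_windows = length(unique(x$eigs$window_ms)),
    explained_1 = x$space$explained_fraction[1],
    explained_2 = x$space$explained_fraction[2],
    prop_complex = mean(x$eigs$complex, na.rm = TRUE))
}
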