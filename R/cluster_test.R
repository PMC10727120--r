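#' Bonferroni-corrected family alpha
#'
#' One-tailed tests over a family of hypotheses (e.g. 2 eigenvalues x 3
#' event locks = 6 age tests, or 3 behavioral measures x 3 locks x 2
#' eigenvalues = 18 behavior tests) use `alpha / n_tests`.
#'
#' @param alpha family-wise alpha (default 0.05).
#' @param n_tests number of tests in the family.
#' @return the corrected per-test alpha.
#' @export
correct_family <- function(alpha = 0.05, n_tests) {
  if (!is_count(n_tests)) stop_invalid("`n_tests` must be a positive integer")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must be in (0, 1)")
  alpha / n_tests
}

#' Cluster-corrected mixed-model test of a time-resolved effect
#'
#' Tests a directional fixed effect on a windowed outcome with the full
#' cluster pipeline: per-window random-intercept mixed models give a
#' fixed-effect t series, 1-D threshold-free cluster enhancement ([tfce_1d()])
#' integrates height and temporal extent, and family-wise significance is
#' calibrated against a bootstrap null built by resampling the predictor
#' across recordings with replacement (keeping each recording's outcome
#' time course and covariates intact, which breaks the predictor-outcome
#' linkage while preserving outcome autocorrelation). Each bootstrap rep
#' refits the mixed model in every window, enhances the tail-oriented t
#' series and records the extreme score; `reps` defaults to 10000.
#' A permutation variant (resampling without replacement) is available via
#' `method = "permutation"` . P-values use the add-one convention
#' `p = (1 + #[null >= observed]) / (1 + reps)` and are compared against
#' `correct_family(alpha, n_tests)`.
#'
#' @inheritParams lmm_timecourse
#' @param tail `"negative"` (effect hypothesized below zero, e.g. eigenvalue
#'   decreasing with age) or `"positive"` (e.g. RT increasing with the
#'   eigenvalue). Stated before testing; the t series is negated internally
#'   for negative tails so enhancement always runs on the hypothesized
#'   direction.
#' @param reps bootstrap replicates (>= 100).
#' @param alpha family-wise alpha before correction.
#' @param n_tests family size for the Bonferroni correction.
#' @param seed integer seed for the bootstrap resampling.
#' @param method `"bootstrap"` (resample predictor with replacement) or
#'   `"permutation"`.
#' @param E,H,nsteps TFCE parameters (defaults 0.5, 2, and `max|t|/100`
#'   threshold steps).
#' @return an `eeg_cluster_test` object: `windows` (tibble with `window_ms`,
#'   `t`, `tfce`, `p`, `sig`), `clusters` (contiguous significant runs),
#'   `null_max` (bootstrap distribution of extreme scores), and the test
#'   specification. Use [generics::tidy()], [generics::glance()] or
#'   [ggplot2::autoplot()] on it.
#' @export
cluster_test <- function(data, outcome, predictor, covariates = NULL,
                         tail = c("negative", "positive"), reps = 10000,
                         alpha = 0.05, n_tests = 1, seed = NULL,
                         method = c("bootstrap", "permutation"),
                         E = 0.5, H = 2, nsteps = 100) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  if (reps < 100) stop_invalid("`reps` must be at least 100")
  alpha_corrected <- correct_family(alpha, n_tests)
  mats <- build_lmm_matrices(data, outcome, predictor, covariates)
  obs <- lmm_t_series_cpp(mats$Y, mats$P, mats$C, mats$g, mats$G, tol = 1e-7)
  tser <- as.numeric(obs$t)
  sgn <- if (tail == "negative") -1 else 1
  oriented <- sgn * tser
  oriented[!is.finite(oriented)] <- 0
  tfce <- tfce_1d(oriented, E = E, H = H, nsteps = nsteps)
  if (!is.null(seed)) set.seed(seed)
  null <- bootstrap_max_tfce_cpp(mats$Y, mats$P, mats$C, mats$g, mats$G,
                                 reps = as.integer(reps), tail = sgn,
                                 E = E, H = H, nsteps = as.integer(nsteps),
                                 permute = (method == "permutation"),
                                 tol = 2e-2)
  null_max <- as.numeric(null$max)
  p <- vapply(tfce, function(s) (1 + sum(null_max >= s)) / (1 + reps), 0)
  sig <- p <= alpha_corrected & tfce > 0
  windows <- tibble::tibble(window_ms = mats$windows, t = tser,
                            tfce = tfce, p = p, sig = sig)
  structure(
    list(windows = windows,
         clusters = summarize_clusters(windows),
         null_max = null_max,
         spec = list(outcome = outcome, predictor = predictor,
                     covariates = covariates, tail = tail, reps = reps,
                     alpha = alpha, n_tests = n_tests,
                     alpha_corrected = alpha_corrected, method = method,
                     seed = seed, redraws = null$redraws,
                     E = E, H = H, nsteps = nsteps,
                     n_recordings = length(mats$recordings),
                     n_participants = length(unique(mats$participants)))),
    class = "eeg_cluster_test")
}

summarize_clusters <- function(windows) {
  r <- rle(windows$sig %in% TRUE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (!length(keep))
    return(tibble::tibble(start_ms = numeric(0), end_ms = numeric(0),
                          n_windows = integer(0), peak_t = numeric(0),
                          peak_tfce = numeric(0), p = numeric(0)))
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    tibble::tibble(start_ms = windows$window_ms[i[1]],
                   end_ms = windows$window_ms[i[length(i)]],
                   n_windows = length(i),
                   peak_t = windows$t[i][which.max(abs(windows$t[i]))],
                   peak_tfce = max(windows$tfce[i]),
                   p = min(windows$p[i]))
  })
}

#' @exportS3Method print eeg_cluster_test
print.eeg_cluster_test <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<eeg_cluster_test> %s ~ %s%s, %s tail, %s null (%d reps)\n",
              s$outcome, s$predictor,
              if (length(s$covariates)) paste0(" + ", paste(s$covariates, collapse = " + ")) else "",
              s$tail, s$method, s$reps))
  cat(sprintf("  alpha %g / %d tests = %.4g; %d/%d windows significant\n",
              s$alpha, s$n_tests, s$alpha_corrected,
              sum(x$windows$sig, na.rm = TRUE), nrow(x$windows)))
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %g..%g ms (p = %.4g)\n",
                  x$clusters$start_ms[i], x$clusters$end_ms[i], x$clusters$p[i]))
  invisible(x)
}
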