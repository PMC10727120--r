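#' Condition-mean residuals of latent single trials
#'
#' Subtracts the same-condition, same-lock trial average from each latent
#' single trial: `x[i,j](t) = s[i,j](t) - mean_j(t)`. The residual is the
#' fluctuation whose relaxation back to the mean evoked trajectory the
#' AR(1) model characterizes. Conditions represented by a single trial
#' yield identically-zero residuals; those trials are flagged
#' (`excluded_from_fit`) and skipped by the window fits.
#'
#' @param latent a `latent_trials` object (see [project_and_zscore()]).
#' @return a `residual_trials` object with the same shape; the trials table
#'   gains an `excluded_from_fit` column.
#' @export
compute_residuals <- function(latent) {
  stopifnot(inherits(latent, "latent_trials"))
  v <- latent$values
  d <- dim(v)
  cond <- as.character(latent$trials$condition)
  excl <- logical(nrow(latent$trials))
  for (k in seq_len(d[2])) {
    M <- matrix(v[, k, ], d[1], d[3])
    for (cd in unique(cond)) {
      i <- which(cond == cd)
      m <- colMeans(M[i, , drop = FALSE])
      M[i, ] <- M[i, , drop = FALSE] - rep(m, each = length(i))
      if (length(i) == 1) excl[i] <- TRUE
    }
    v[, k, ] <- M
  }
  tr <- dplyr::mutate(latent$trials, excluded_from_fit = excl)
  structure(
    list(values = v, fs = latent$fs, lock = latent$lock, times = latent$times,
         trials = tr, recording = latent$recording),
    class = c("residual_trials"))
}

#' Least-squares AR(1) fit in one moving window
#'
#' Fits the first-order linear dynamical system `x(t+1) = A x(t) + eps(t)`
#' to the 2-D residual activity, pooling transition pairs from all trials
#' and all conditions whose both endpoints lie inside a window of `width`
#' ms centred at `window_center`. The estimate is the ordinary
#' least-squares solution of the 2x2 normal equations,
#' `A = (sum y x') (sum x x')^-1` with `y = x(t+1)`; no intercept is
#' included because residuals are mean-zero by construction. At 30 Hz a
#' 100 ms window holds three samples per trial, i.e. two transition pairs
#' per trial.
#'
#' @param residuals a `residual_trials` object.
#' @param window_center window centre in ms relative to the lock event.
#' @param width window width in ms (default 100).
#' @param min_pairs minimum pooled transition pairs needed to report a fit
#'   (default 4, the parameter count of A); below it the window is skipped
#'   (`A_hat` is NA) with a log message.
#' @return list with `A_hat` (2x2 matrix, or NA matrix when skipped) and
#'   `n_pairs`.
#' @export
fit_window_ar1 <- function(residuals, window_center, width = 100, min_pairs = 4) {
  stopifnot(inherits(residuals, "residual_trials"))
  tol <- 1e-6
  idx <- which(abs(residuals$times - window_center) <= width / 2 + tol)
  if (length(idx) < 2)
    stop_invalid("window does not contain at least two samples")
  keep <- !isTRUE_vec(residuals$trials$excluded_from_fit)
  v <- residuals$values[keep, , , drop = FALSE]
  # consecutive-sample pairs with both endpoints inside the window
  from <- idx[-length(idx)]
  to <- idx[-1]
  ok <- to == from + 1
  from <- from[ok]; to <- to[ok]
  n_pairs <- dim(v)[1] * length(from)
  if (n_pairs < min_pairs) {
    message(sprintf(
      "fit_window_ar1: window at %g ms skipped (%d pairs < %d)",
      window_center, n_pairs, min_pairs))
    return(list(A_hat = matrix(NA_real_, 2, 2), n_pairs = n_pairs))
  }
  X <- rbind(as.vector(v[, 1, from]), as.vector(v[, 2, from]))
  Y <- rbind(as.vector(v[, 1, to]), as.vector(v[, 2, to]))
  Sxx <- tcrossprod(X)
  if (rcond(Sxx) < 1e-12)
    stop_numerical(sprintf(
      "singular pooled second-moment matrix in window at %g ms", window_center))
  list(A_hat = tcrossprod(Y, X) %*% solve(Sxx), n_pairs = n_pairs)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Order the eigenpairs of a 2x2 dynamics matrix by component association
#'
#' Eigenpairs are labeled so that eigenvalue k is the one whose eigenvector
#' loads maximally on principal component k; when both eigenvectors claim
#' the same component, the one with the larger absolute loading wins and
#' the other takes the remaining slot. A complex-conjugate pair shares one
#' modulus: both slots report that modulus, `complex` is set, and the
#' assignment uses the real parts of the eigenvectors. The scalar reported
#' per mode is the eigenvalue modulus — the per-step decay factor of the
#' mode, equal to the eigenvalue itself when real and non-negative.
#'
#' @param A_hat real 2x2 matrix.
#' @return list with `moduli` (length 2, ordered by component slot),
#'   `vectors` (2x2 real matrix, columns are the slot-ordered eigenvector
#'   directions, unit norm, own-component loading made non-negative),
#'   `values` (the complex eigenvalues in slot order) and `complex` flag.
#' @export
order_eigs <- function(A_hat) {
  stopifnot(is.matrix(A_hat), all(dim(A_hat) == 2))
  ev <- eig2x2(A_hat)
  cplx <- ev$complex
  V <- ev$vectors
  claim <- c(which.max(abs(V[, 1])), which.max(abs(V[, 2])))
  if (claim[1] != claim[2]) {
    ord <- order(claim)
  } else {
    p <- claim[1]
    winner <- which.max(abs(V[p, ]))
    ord <- if (p == 1) c(winner, 3 - winner) else c(3 - winner, winner)
  }
  V <- V[, ord, drop = FALSE]
  vals <- ev$values[ord]
  for (k in 1:2) if (V[k, k] < 0) V[, k] <- -V[, k]
  list(moduli = Mod(vals), vectors = V, values = vals, complex = cplx)
}

#' Sliding-window AR(1) eigenvalue time course
#'
#' Applies [fit_window_ar1()] at every window position across the lock
#' segment, producing the time-dependent estimate of the dynamics matrix
#' and its component-ordered eigenvalue moduli. Windows are labeled by
#' their centre time; the default step is one sample (~33 ms at 30 Hz),
#' the finest available grid.
#'
#' @inheritParams fit_window_ar1
#' @param width window width in ms.
#' @param step_samples step between window centres, in samples.
#' @return tibble with one row per window: `window_ms`, the entries of
#'   `A_hat` (`a11`..`a22`), `eig1`, `eig2` (moduli, component-ordered),
#'   eigenvector loadings (`v11`, `v21`, `v12`, `v22` with `vKJ` the K-th
#'   component loading of slot-J's eigenvector), `complex`, `n_pairs`.
#'   Skipped windows carry NA estimates.
#' @export
sweep_dynamics <- function(residuals, width = 100, step_samples = 1, min_pairs = 4) {
  stopifnot(inherits(residuals, "residual_trials"))
  tms <- residuals$times
  dt <- 1000 / residuals$fs
  half <- floor((width / 2) / dt + 1e-9)
  if (half < 1) stop_invalid("window width below two samples at this rate")
  nt <- length(tms)
  centers_i <- seq(1 + half, nt - half, by = step_samples)
  if (!length(centers_i)) stop_invalid("segment shorter than one window")
  keep <- !isTRUE_vec(residuals$trials$excluded_from_fit)
  v <- residuals$values[keep, , , drop = FALSE]
  n <- dim(v)[1]
  a <- matrix(v[, 1, ], nrow = n); b <- matrix(v[, 2, ], nrow = n)
  res <- sweep_dynamics_core_cpp(a, b, half = as.integer(half),
                                 step = as.integer(step_samples),
                                 min_pairs = as.integer(min_pairs))
  if (any(res$singular == 1)) {
    w <- which(res$singular == 1)[1]
    stop_numerical(sprintf(
      "singular pooled second-moment matrix in window at %g ms",
      tms[res$centers[w]]))
  }
  skipped <- which(res$n_pairs < min_pairs)
  if (length(skipped))
    message(sprintf("sweep_dynamics: %d window(s) skipped (fewer than %d pairs)",
                    length(skipped), min_pairs))
  out <- res$out
  nw <- nrow(out)
  tibble::new_tibble(list(
    window_ms = tms[res$centers],
    a11 = out[, 1], a12 = out[, 2], a21 = out[, 3], a22 = out[, 4],
    eig1 = out[, 5], eig2 = out[, 6],
    v11 = out[, 7], v21 = out[, 8], v12 = out[, 9], v22 = out[, 10],
    complex = as.logical(res$complex), n_pairs = as.integer(res$n_pairs)),
    nrow = nw)
}

#' Construct residual trials directly
#'
#' Mostly useful for simulation studies in which residual fluctuations are
#' generated with known dynamics and fed straight to the window fits,
#' bypassing the projection/z-scoring stages.
#'
#' @inheritParams latent_trials
#' @param trials optional trials tibble; by default all trials share one
#'   condition and are eligible for fitting.
#' @return a `residual_trials` object.
#' @export
residual_trials <- function(values, fs, lock = "stimulus", times,
                            trials = NULL, recording = list()) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_invalid("`values` must be a trials x components x time array")
  if (is.null(trials))
    trials <- tibble::tibble(
      condition = rep("congruent_correct", dim(values)[1]),
      rt_ms = NA_real_, responded = TRUE,
      excluded_from_fit = FALSE)
  structure(
    list(values = values, fs = fs, lock = lock, times = as.numeric(times),
         trials = tibble::as_tibble(trials), recording = recording),
    class = "residual_trials")
}
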