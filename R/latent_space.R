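#' Fit the 2-component sensor-space PCA from grand-average ERPs
#'
#' The spatial reduction is fit once, on the time-concatenated grand-average
#' condition ERPs (by default the stimulus- and response-locked conditions),
#' and reused unchanged for every subject and age. The sensors-by-sensors
#' covariance of the concatenated, time-mean-centered condition means is
#' eigendecomposed and the top two eigenvectors retained. Eigenvector signs
#' are fixed deterministically: the sensor with the largest absolute loading
#' is made positive.
#'
#' @param grand_averages named list of `sensors x time` matrices, one per
#'   lock/condition cell entering the fit (see [grand_average_erps()]).
#' @param n_components number of retained components (fixed at 2 for the
#'   dynamics analysis).
#' @return a `component_space` object: `loadings` (`sensors x 2`,
#'   orthonormal columns), `explained_fraction` (non-increasing), and
#'   `fit_provenance` (names of the blocks that entered the fit).
#' @export
fit_component_space <- function(grand_averages, n_components = 2) {
  stopifnot(is.list(grand_averages), length(grand_averages) >= 1)
  ns <- vapply(grand_averages, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop_invalid("all grand averages must share the sensor count")
  X <- do.call(cbind, grand_averages)
  if (ncol(X) < 2) stop_invalid("need at least 2 time points in total")
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / (ncol(Xc) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  if (lam[n_components] <= 1e-12 * max(lam, 1e-300))
    stop_invalid(sprintf("grand-average covariance has rank < %d", n_components))
  loadings <- ev$vectors[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    s <- sign(loadings[which.max(abs(loadings[, k])), k])
    loadings[, k] <- loadings[, k] * s
  }
  structure(
    list(loadings = loadings,
         explained_fraction = lam[seq_len(n_components)] / sum(lam),
         fit_provenance = names(grand_averages) %||% rep("", length(grand_averages))),
    class = "component_space")
}

#' @exportS3Method print component_space
print.component_space <- function(x, ...) {
  cat(sprintf("<component_space> %d sensors, %d components; explained: %s\n",
              nrow(x$loadings), ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", ")))
  invisible(x)
}

#' Grand-average condition ERPs across a cohort
#'
#' Per-condition mean ERPs pooled over all trials and recordings, for the
#' requested locks. Each lock/condition cell yields one `sensors x time`
#' matrix; the four task conditions are weighted equally in the
#' concatenation used by [fit_component_space()].
#'
#' @param epochs_list list of segmented [eeg_epochs] (any mix of recordings
#'   and locks).
#' @param locks locks entering the average (default stimulus and response;
#'   cue-locked data are projected with the resulting space but excluded
#'   from its fit).
#' @return named list of `sensors x time` matrices (`lock.condition`).
#' @export
grand_average_erps <- function(epochs_list, locks = c("stimulus", "response")) {
  epochs_list <- epochs_list[vapply(epochs_list, function(e) e$lock, "") %in% locks]
  if (!length(epochs_list)) stop_invalid("no epochs for the requested locks")
  out <- list()
  for (lk in locks) {
    els <- epochs_list[vapply(epochs_list, function(e) e$lock, "") == lk]
    if (!length(els)) next
    for (cond in condition_levels()) {
      acc <- NULL; n <- 0
      for (e in els) {
        i <- which(e$trials$condition == cond)
        if (!length(i)) next
        s <- colSums(array(e$data[i, , , drop = FALSE],
                           c(length(i), dim(e$data)[2], dim(e$data)[3])), dims = 1)
        acc <- if (is.null(acc)) s else acc + s
        n <- n + length(i)
      }
      if (n > 0) out[[paste(lk, cond, sep = ".")]] <- acc / n
    }
  }
  out
}

#' Project epochs into component space and z-score per subject
#'
#' Each time point of each trial is projected onto the two spatial
#' components, then each component is standardized with a single mean and SD
#' per subject, pooled over *all* trials and time points of the session
#' (across every lock supplied). A per-timepoint standardization would
#' destroy the temporal structure the dynamics model measures, so it is
#' deliberately not offered.
#'
#' @param epochs an [eeg_epochs] or a (possibly named) list of them from the
#'   same recording — supply all locks of a session together so the
#'   standardization is session-wide.
#' @param space a `component_space` from [fit_component_space()].
#' @return a `latent_trials` object (or list of them, matching the input):
#'   `values` is `trials x 2 x time` in z-units; `zscore_params` records the
#'   per-component mean and SD used.
#' @export
project_and_zscore <- function(epochs, space) {
  single <- inherits(epochs, "eeg_epochs")
  eps <- if (single) list(epochs) else epochs
  stopifnot(inherits(space, "component_space"))
  k <- ncol(space$loadings)
  proj <- lapply(eps, function(e) {
    if (dim(e$data)[2] != nrow(space$loadings))
      stop_invalid("sensor count does not match the component space")
    d <- dim(e$data)
    flat <- matrix(aperm(e$data, c(2, 1, 3)), nrow = d[2])  # sensors x (trial*time)
    lat <- crossprod(space$loadings, flat)                  # k x (trial*time)
    aperm(array(lat, c(k, d[1], d[3])), c(2, 1, 3))
  })
  mu <- vn <- numeric(k); ntot <- 0
  for (p in proj) for (j in seq_len(k)) mu[j] <- mu[j] + sum(p[, j, ])
  ntot <- sum(vapply(proj, function(p) prod(dim(p)[c(1, 3)]), 0))
  mu <- mu / ntot
  for (p in proj) for (j in seq_len(k)) vn[j] <- vn[j] + sum((p[, j, ] - mu[j])^2)
  sdv <- sqrt(vn / ntot)
  if (any(sdv <= 0)) {
    flat_k <- which(sdv <= 0)
    stop_numerical(paste0("component ", paste(flat_k, collapse = ", "),
                          " has zero pooled SD; cannot z-score"))
  }
  out <- purrr::map2(proj, eps, function(p, e) {
    for (j in seq_len(k)) p[, j, ] <- (p[, j, ] - mu[j]) / sdv[j]
    latent_trials(p, fs = e$fs, lock = e$lock, times = e$times,
                  trials = e$trials, recording = e$recording,
                  zscore_params = list(mean = mu, sd = sdv))
  })
  if (single) out[[1]] else out
}

#' Latent (component-space) single trials
#'
#' @param values numeric array `trials x components x time` (z-units once
#'   standardized).
#' @inheritParams eeg_epochs
#' @param zscore_params list with per-component `mean` and `sd` used for
#'   standardization (NULL when not yet standardized).
#' @return an object of class `latent_trials`.
#' @export
latent_trials <- function(values, fs, lock, times, trials, recording,
                          zscore_params = NULL) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop_invalid("`values` must be a trials x components x time array")
  structure(
    list(values = values, fs = fs, lock = lock, times = as.numeric(times),
         trials = tibble::as_tibble(trials), recording = recording,
         zscore_params = zscore_params),
    class = "latent_trials")
}

#' @exportS3Method print latent_trials
print.latent_trials <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<latent_trials> %s-locked: %d trials x %d components x %d samples @ %g Hz\n",
              x$lock, d[1], d[2], d[3], x$fs))
  invisible(x)
}
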