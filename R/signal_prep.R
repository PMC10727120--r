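#' Zero-phase lowpass filter and downsample epoched EEG
#'
#' Applies a zero-phase (forward-backward) Butterworth lowpass and resamples
#' each trial onto the target analysis grid. The evoked-response spectrum is
#' dominated by frequencies below 10 Hz, so the default 15 Hz cutoff and
#' 30 Hz analysis rate retain the ERP while discarding high-frequency
#' content. The filter family and order are a package default (4th-order
#' Butterworth); zero-phase application avoids the phase distortion that
#' would bias the downstream dynamics estimates.
#'
#' Edges are reflect-padded before filtering; if the epoch is shorter than
#' the pad a warning is issued and the available length is used. After
#' filtering, samples are interpolated onto the target grid (aligned so that
#' t = 0 ms is a sample); since all remaining energy lies below the cutoff,
#' linear interpolation is accurate there.
#'
#' @param epochs an [eeg_epochs] object.
#' @param cutoff lowpass cutoff in Hz (default 15).
#' @param target_fs target sampling rate in Hz (default 30).
#' @param order Butterworth order (default 4, applied twice).
#' @return an [eeg_epochs] at `target_fs`, metadata preserved.
#' @export
lowpass_downsample <- function(epochs, cutoff = 15, target_fs = 30, order = 4) {
  fs <- epochs$fs
  if (cutoff >= fs / 2)
    stop_invalid(sprintf("cutoff (%g Hz) must be below the input Nyquist (%g Hz)", cutoff, fs / 2))
  if (fs < 2 * cutoff)
    stop_invalid("input sampling rate must be at least twice the cutoff")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- ceiling(3 * fs / cutoff)
  nt <- dim(epochs$data)[3]
  if (pad >= nt) {
    rlang::warn("epoch shorter than the filter pad; reflect-padding with the full epoch")
    pad <- nt - 1
  }
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = nt)  # time x (trial*sensor)
  filt1 <- function(v) {
    vp <- c(2 * v[1] - v[pad:1 + 1], v, 2 * v[nt] - v[nt - (1:pad)])
    # demean so startup transients act on a zero-mean signal; the filter has
    # unit DC gain, so the mean passes through unchanged
    mu <- mean(vp)
    y <- signal::filter(bf, vp - mu)
    y <- rev(signal::filter(bf, rev(y)))
    y[(pad + 1):(pad + nt)] + mu
  }
  flat <- apply(flat, 2, filt1)
  tt <- time_grid(min(epochs$times), max(epochs$times), target_fs)
  out <- apply(flat, 2, function(v) approx(epochs$times, v, xout = tt)$y)
  arr <- aperm(array(out, c(length(tt), d[1], d[2])), c(2, 3, 1))
  eeg_epochs(arr, fs = target_fs, lock = epochs$lock, times = tt,
             trials = epochs$trials, recording = epochs$recording)
}

#' Frequency response of the preprocessing lowpass
#'
#' Amplitude response of the zero-phase Butterworth used by
#' [lowpass_downsample()] at the requested frequencies (the squared
#' single-pass magnitude, since the filter is applied forward and backward).
#'
#' @param freqs frequencies in Hz.
#' @inheritParams lowpass_downsample
#' @param fs sampling rate of the data the filter is designed for.
#' @return numeric vector of amplitude gains in `[0, 1]`.
#' @export
lowpass_response <- function(freqs, fs, cutoff = 15, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  vapply(2 * pi * freqs / fs, function(w) {
    zb <- exp(-1i * w * (seq_along(bf$b) - 1))
    za <- exp(-1i * w * (seq_along(bf$a) - 1))
    Mod(sum(bf$b * zb) / sum(bf$a * za))^2
  }, 0)
}

#' Re-segment epochs onto a lock-specific analysis window
#'
#' Slices each trial onto the analysis window for the requested event lock
#' and drops trials without a button response (all correct and commission
#' error trials are retained in both congruency conditions). With inclusive
#' endpoints the window contains `round((end - start)/1000 * fs) + 1`
#' samples.
#'
#' @param epochs an [eeg_epochs] object.
#' @param lock event lock; defaults to the lock the epochs carry.
#' @param windows named list of `(start_ms, end_ms)` per lock, see
#'   [lock_windows()].
#' @return an [eeg_epochs] restricted to the window and to responded trials.
#' @export
segment_epochs <- function(epochs, lock = epochs$lock, windows = lock_windows()) {
  lock <- match.arg(lock, names(windows))
  win <- windows[[lock]]
  if (win[1] >= win[2]) stop_invalid("lock window must have start < end")
  fs <- epochs$fs
  n_expect <- round((win[2] - win[1]) / 1000 * fs) + 1
  tol <- 1e-6 * max(1, fs)
  idx <- which(epochs$times >= win[1] - tol & epochs$times <= win[2] + tol)
  if (length(idx) < n_expect)
    stop_invalid(sprintf(
      "epoch extent (%g..%g ms) does not cover the %s window (%g..%g ms)",
      min(epochs$times), max(epochs$times), lock, win[1], win[2]))
  idx <- idx[seq_len(n_expect)]
  keep <- which(epochs$trials$responded %in% TRUE)
  if (!length(keep))
    stop_invalid("no responded trials available for this lock")
  dropped <- nrow(epochs$trials) - length(keep)
  if (dropped > 0)
    message("segment_epochs: dropped ", dropped, " trial(s) without a response")
  new_eeg_epochs(epochs$data[keep, , idx, drop = FALSE], fs = fs, lock = lock,
                 times = epochs$times[idx],
                 trials = epochs$trials[keep, , drop = FALSE],
                 recording = epochs$recording)
}

#' Minimum-trial inclusion rule, applied per event lock
#'
#' Recordings contribute to a lock-specific analysis only if they retain at
#' least `min_trials` clean trials after segmentation for that lock; a
#' recording excluded for one lock can still enter the others.
#'
#' @param counts data frame with columns `recording_id`, `lock`, `n_trials`
#'   (counts computed after segmentation).
#' @param min_trials inclusion threshold (default 50, inclusive).
#' @return the input tibble with a logical `included` column.
#' @export
apply_inclusion_rule <- function(counts, min_trials = 50) {
  stopifnot(all(c("recording_id", "lock", "n_trials") %in% names(counts)))
  dplyr::mutate(tibble::as_tibble(counts), included = .data$n_trials >= min_trials)
}
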