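#' Epoched multi-sensor EEG trials
#'
#' Container for artifact-cleaned, event-locked EEG trials from one
#' recording session: a `trials x sensors x time` array plus per-trial and
#' per-recording metadata. Trials are time-locked to one of the task events
#' (fixation cue, flanker stimulus, or button response).
#'
#' @param data numeric array `trials x sensors x time` (microvolts or any
#'   consistent unit; downstream z-scoring removes the scale).
#' @param fs sampling rate in Hz.
#' @param lock event lock, one of `"cue"`, `"stimulus"`, `"response"`.
#' @param times numeric vector of sample times in ms relative to the lock
#'   event; length must match `dim(data)[3]`.
#' @param trials tibble with one row per trial: columns `condition` (one of
#'   the four congruency-by-outcome labels), `rt_ms`, `responded`.
#' @param recording list with `recording_id`, `participant`, `age` (years,
#'   real-valued), `sex`, `wave`.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, lock, times, trials, recording) {
  lock <- match.arg(lock, c("cue", "stimulus", "response"))
  if (!is.array(data) || length(dim(data)) != 3)
    stop_invalid("`data` must be a trials x sensors x time array")
  if (length(times) != dim(data)[3])
    stop_invalid("`times` length must equal the time dimension of `data`")
  if (!is.data.frame(trials) || nrow(trials) != dim(data)[1])
    stop_invalid("`trials` must have one row per trial")
  if (!all(c("condition", "rt_ms", "responded") %in% names(trials)))
    stop_invalid("`trials` needs columns condition, rt_ms, responded")
  bad <- setdiff(unique(as.character(trials$condition)), condition_levels())
  if (length(bad))
    stop_invalid(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")))
  if (any(trials$responded & !is.na(trials$rt_ms) & trials$rt_ms <= 0))
    stop_invalid("rt_ms must be > 0 for responded trials")
  structure(
    list(data = data, fs = fs, lock = lock, times = as.numeric(times),
         trials = tibble::as_tibble(trials), recording = recording),
    class = "eeg_epochs")
}

# internal fast constructor: callers guarantee validity (simulation and
# segmentation reuse already-validated pieces in hot loops)
new_eeg_epochs <- function(data, fs, lock, times, trials, recording) {
  structure(
    list(data = data, fs = fs, lock = lock, times = as.numeric(times),
         trials = trials, recording = recording),
    class = "eeg_epochs")
}

#' The four task condition labels
#'
#' Flanker congruency crossed with response outcome (correct vs commission
#' error). Omission (no-response) trials carry a label too but are dropped
#' at segmentation.
#' @return character vector of length 4
#' @export
condition_levels <- function() {
  c("congruent_correct", "congruent_error",
    "incongruent_correct", "incongruent_error")
}

#' @exportS3Method print eeg_epochs
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %s-locked: %d trials x %d sensors x %d samples @ %g Hz\n",
              x$lock, d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g..%g ms; participant %s, age %.1f, wave %s\n",
              min(x$times), max(x$times),
              x$recording$participant %||% "?",
              x$recording$age %||% NA_real_,
              x$recording$wave %||% "?"))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

#' Default event-lock analysis windows
#'
#' Cue-locked trials are analysed from -600 to 500 ms, stimulus-locked from
#' -400 to 600 ms and response-locked from -500 to 500 ms, all relative to
#' the locking event.
#'
#' @return named list of `(start_ms, end_ms)` pairs
#' @export
lock_windows <- function() {
  list(cue = c(-600, 500), stimulus = c(-400, 600), response = c(-500, 500))
}
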