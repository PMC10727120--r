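#' Per-recording behavioral summary tables
#'
#' Accuracy, mean reaction time and reaction-time SD per recording, overall
#' and split by flanker congruency, computed over responded trials. These
#' summaries feed the behavior mixed models (`RT ~ eigenvalue`,
#' `Accuracy ~ eigenvalue`, `RT SD ~ eigenvalue`).
#'
#' @param trials data frame of trial metadata with columns `recording_id`,
#'   `participant`, `age`, `sex`, `wave`, `condition`, `rt_ms`,
#'   `responded` — e.g. the `$trials` table of a simulated cohort, or rows
#'   bound from `eeg_epochs$trials`.
#' @return tibble with one row per recording: `accuracy`, `rt_mean`,
#'   `rt_sd`, plus `_congruent` / `_incongruent` splits and trial counts.
#' @export
behavior_tables <- function(trials) {
  need <- c("recording_id", "participant", "age", "condition", "rt_ms", "responded")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_invalid(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  tr <- dplyr::filter(tibble::as_tibble(trials), .data$responded %in% TRUE)
  tr <- dplyr::mutate(
    tr,
    congruent = grepl("^congruent", as.character(.data$condition)),
    correct = grepl("correct$", as.character(.data$condition)))
  meta_cols <- intersect(c("participant", "age", "sex", "wave"), names(tr))
  overall <- tr |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta_cols), dplyr::first),
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      rt_mean = mean(.data$rt_ms),
      rt_sd = sd_or_zero(.data$rt_ms),
      .groups = "drop")
  split <- tr |>
    dplyr::group_by(.data$recording_id, .data$congruent) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     rt_mean = mean(.data$rt_ms),
                     rt_sd = sd_or_zero(.data$rt_ms), .groups = "drop") |>
    dplyr::mutate(cond = ifelse(.data$congruent, "congruent", "incongruent")) |>
    dplyr::select(-"congruent") |>
    tidyr::pivot_wider(names_from = "cond",
                       values_from = c("accuracy", "rt_mean", "rt_sd"))
  dplyr::left_join(overall, split, by = "recording_id")
}

# sd() of a length-1 vector is NA; identical RTs have SD 0 by definition
sd_or_zero <- function(x) {
  if (length(x) < 2) return(0)
  s <- stats::sd(x)
  if (is.na(s)) 0 else s
}
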