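#' Simulate a longitudinal EEG cohort with known dynamics
#'
#' Realizes the forward model behind the analysis pipeline: per trial, a
#' latent 2-D residual fluctuation `x(t)` evolves by
#' `x(t+1) = A x(t) + eps(t)` with i.i.d. Gaussian innovations and the
#' ground-truth, possibly age- and time-dependent dynamics matrix; the
#' sensor signal is `loadings %*% (template_j(t) + x(t))` plus white sensor
#' noise. Trial metadata (condition, RT, response flag) and recording
#' metadata (participant, age, sex, wave) are generated alongside, with
#' session RT and accuracy coupled to the session's ground-truth eigenvalue
#' through [simulate_behavior()]. Subjects skip waves independently with
#' the configured missingness.
#'
#' The latent process is generated on the 30 Hz analysis grid where the
#' ground-truth dynamics are defined. With `fs_raw` above 30 Hz the sensor
#' signals are interpolated onto the acquisition grid (the signal is
#' band-limited well below the 15 Hz analysis cutoff, so the preprocessing
#' filter is transparent to it); with `fs_raw = 30` data are returned on
#' the analysis grid directly.
#'
#' The global seed fans out into per-subject, per-wave substreams, so the
#' same subject receives identical data regardless of cohort subsetting,
#' and the whole cohort is byte-identical across runs with the same
#' config.
#'
#' @param config a [cohort_config()].
#' @param truth a [ground_truth_dynamics()].
#' @param locks event locks to generate (default all three).
#' @param pad_ms extra epoch padding beyond the lock analysis window.
#' @return an `eeg_cohort`: tibble with one row per recording session
#'   (`recording_id`, `participant`, `age`, `sex`, `wave`,
#'   `truth_eig1`, `truth_eig2` at the stimulus epoch, `epochs` list-column
#'   of per-lock [eeg_epochs]), with the config and truth attached as
#'   attributes.
#' @export
simulate_cohort <- function(config, truth,
                            locks = c("cue", "stimulus", "response"),
                            pad_ms = 100) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(truth, "ground_truth_dynamics"))
  check_truth_stability(truth)
  wins <- lock_windows()
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    set.seed(sub_seed(config$seed, i, 0L))
    sex <- sample(c("F", "M"), 1)
    offs <- rnorm(2, 0, truth$subject_sd)
    attended <- runif(length(config$waves)) >= config$missingness
    ages <- config$waves + rnorm(length(config$waves), 0, config$age_sd)
    for (w in seq_along(config$waves)) {
      if (!attended[w]) next
      set.seed(sub_seed(config$seed, i, w))
      rows[[length(rows) + 1]] <-
        simulate_session(config, truth, locks, wins, pad_ms,
                         subject = i, wave = w, age = ages[w],
                         sex = sex, offsets = offs)
    }
  }
  if (!length(rows)) stop_invalid("cohort is empty (missingness too high?)")
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "config") <- config
  attr(cohort, "truth") <- truth
  class(cohort) <- c("eeg_cohort", class(cohort))
  cohort
}

simulate_session <- function(config, truth, locks, wins, pad_ms,
                             subject, wave, age, sex, offsets) {
  rid <- sprintf("S%04d_w%d", subject, wave)
  # session-level ground-truth eigenvalues: stimulus epoch + subject offset
  A_stim <- truth$A_of_t("stimulus", 0, age)
  sess_eig <- clip01(sort(Mod(eig2x2(A_stim)$values), decreasing = TRUE) + offsets)
  beh <- simulate_behavior(truth, sess_eig[2], age)
  n <- config$n_trials
  # congruency from the configured marginals; correctness re-centred on the
  # session's coupled accuracy so behavior effects are recoverable from trials
  p <- config$condition_probs
  p_cong <- p[1] + p[2]
  base_acc <- c(cong = p[[1]] / (p[[1]] + p[[2]]), incong = p[[3]] / (p[[3]] + p[[4]]))
  marginal_acc <- p_cong * base_acc[["cong"]] + (1 - p_cong) * base_acc[["incong"]]
  congruent <- runif(n) < p_cong
  p_correct <- pmin(pmax(ifelse(congruent, base_acc[["cong"]], base_acc[["incong"]]) +
                           (beh$accuracy - marginal_acc), 0.01), 1)
  correct <- runif(n) < p_correct
  cond <- paste0(ifelse(congruent, "congruent", "incongruent"),
                 ifelse(correct, "_correct", "_error"))
  responded <- runif(n) >= config$omission_prob
  rt <- beh$mean_rt + 25 * ifelse(congruent, -1, 1) +
    rnorm(n, 0, truth$rt_trial_sd_ms)
  rt <- pmax(rt, 150)
  rt[!responded] <- NA_real_
  trials <- tibble::new_tibble(list(trial = seq_len(n), condition = cond,
                                    congruent = congruent, correct = correct,
                                    rt_ms = rt, responded = responded),
                               nrow = n)
  recording <- list(recording_id = rid, participant = sprintf("P%04d", subject),
                    age = age, sex = sex, wave = wave)
  epochs <- lapply(setNames(locks, locks), function(lk)
    simulate_lock_epochs(config, truth, lk, wins[[lk]], pad_ms, trials,
                         recording, age, offsets))
  tibble::new_tibble(list(
    recording_id = rid, participant = recording$participant,
    age = age, sex = sex, wave = wave,
    truth_eig1 = sess_eig[1], truth_eig2 = sess_eig[2],
    accuracy_true = beh$accuracy, rt_true = beh$mean_rt,
    epochs = list(epochs)), nrow = 1L)
}

simulate_lock_epochs <- function(config, truth, lock, win, pad_ms, trials,
                                 recording, age, offsets) {
  fs_gen <- 30
  tms <- time_grid(win[1] - pad_ms, win[2] + pad_ms, fs_gen)
  nt <- length(tms)
  n <- nrow(trials)
  # per-window dynamics with the subject offset on the diagonal, kept stable
  stabilize <- function(t_ms) {
    A <- truth$A_of_t(lock, t_ms, age) + diag(offsets)
    r <- spectral_radius(A)
    if (r >= 0.98) A <- A * (0.97 / r)
    A
  }
  A0 <- stabilize(tms[1])
  time_varying <- !identical(A0, stabilize(tms[ceiling(nt / 2)])) ||
    !identical(A0, stabilize(tms[nt]))
  A_list <- if (time_varying) lapply(tms, stabilize) else
    rep(list(A0), nt)
  # stationary start, AR propagation, template addition and sensor mixing
  # happen in the compiled kernel (R-RNG reproducible)
  P0 <- stationary_cov(A_list[[1]], max(truth$noise_sd, 1e-12)^2)
  R0 <- if (truth$noise_sd > 0) chol(P0) else matrix(0, 2, 2)
  tpl <- lapply(setNames(condition_levels(), condition_levels()),
                function(cd) truth$erp_templates(lock, cd, tms))
  tpl_cube <- array(0, c(2, nt, 4))
  for (k in seq_along(condition_levels())) tpl_cube[, , k] <- tpl[[k]]
  cidx <- match(trials$condition, condition_levels()) - 1L
  Amats <- if (length(A_list) == 1 || !time_varying)
    array(A_list[[1]], c(2, 2, 1))
  else array(unlist(A_list[-nt]), c(2, 2, nt - 1))
  ns <- config$n_sensors
  arr <- sim_lock_core_cpp(Amats, R0, truth$noise_sd, truth$sensor_loadings,
                           tpl_cube, cidx, truth$sensor_noise_sd)
  if (config$fs_raw > fs_gen + 1e-9) {
    t_raw <- time_grid(min(tms), max(tms), config$fs_raw)
    flat2 <- matrix(aperm(arr, c(3, 1, 2)), nrow = nt)
    up <- apply(flat2, 2, function(v) approx(tms, v, xout = t_raw)$y)
    arr <- aperm(array(up, c(length(t_raw), n, ns)), c(2, 3, 1))
    tms <- t_raw
  }
  new_eeg_epochs(arr,
                 fs = if (config$fs_raw > fs_gen + 1e-9) config$fs_raw else fs_gen,
                 lock = lock, times = tms, trials = trials,
                 recording = recording)
}

clip01 <- function(x) pmin(pmax(x, 0), 0.97)

#' Session behavior coupled to a ground-truth eigenvalue
#'
#' Generates a session's mean RT and accuracy from its eigenvalue: slower
#' relaxation (larger eigenvalue) means slower and less accurate
#' responding. The eigenvalue is z-scored against the cohort population
#' (`eig_pop_mean`, `eig_pop_sd`); mean RT moves `rt_coupling` of its
#' between-session SD per SD of eigenvalue (plus an age trend and session
#' noise), so regressing standardized RT on the standardized eigenvalue
#' across sessions recovers `rt_coupling` as the slope. Accuracy decreases
#' linearly and is clipped to `[0, 1]`.
#'
#' @param truth a [ground_truth_dynamics()].
#' @param per_session_eigenvalue the session's eigenvalue, in `[0, 1)`.
#' @param age session age in years.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return list with `mean_rt` (ms) and `accuracy` (fraction).
#' @export
simulate_behavior <- function(truth, per_session_eigenvalue, age, seed = NULL) {
  if (!is.numeric(per_session_eigenvalue) ||
      per_session_eigenvalue < 0 || per_session_eigenvalue >= 1)
    stop_invalid("per_session_eigenvalue must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  z <- (per_session_eigenvalue - truth$eig_pop_mean) / truth$eig_pop_sd
  rho <- truth$rt_coupling
  rt_z <- rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(1)
  mean_rt <- truth$rt_base_ms - truth$rt_age_slope * (age - truth$ref_age) +
    truth$rt_sd_ms * rt_z
  accuracy <- truth$acc_base + truth$acc_age_slope * (age - truth$ref_age) -
    truth$acc_coupling * z + rnorm(1, 0, truth$acc_noise_sd)
  list(mean_rt = mean_rt, accuracy = min(max(accuracy, 0), 1))
}

#' Jitter configuration for the latency-jitter control
#'
#' The control datasets replace every single trial by the condition-mean
#' ERP shifted in time by a trial-specific offset `tau ~ N(0, sigma_age)`
#' plus white noise; `sigma_by_age` defaults to the reaction-time SDs of
#' the three age groups (97, 76 and 72 ms at ages 12, 15, 18).
#'
#' @param sigma_by_age named vector of jitter SDs in ms, names are target
#'   ages.
#' @param eps_sd SD of the additive Gaussian noise (z-units, matched to the
#'   typical residual SD of the analysed data).
#' @return a `jitter_config` list.
#' @export
jitter_config <- function(sigma_by_age = c("12" = 97, "15" = 76, "18" = 72),
                          eps_sd = 1) {
  if (any(sigma_by_age < 0) || eps_sd < 0)
    stop_invalid("jitter SDs and eps_sd must be non-negative")
  if (is.null(names(sigma_by_age)))
    stop_invalid("sigma_by_age must be named by target age")
  structure(list(sigma_by_age = sigma_by_age, eps_sd = eps_sd),
            class = "jitter_config")
}

#' Generate a latency-jittered control dataset for one session
#'
#' Each trial is the condition-mean latent ERP evaluated at shifted times
#' `t + tau`, with `tau` drawn per trial from a zero-mean Gaussian whose SD
#' is the age group's entry in the jitter config, plus i.i.d. Gaussian
#' noise. The shift is implemented by linear interpolation with
#' nearest-value edge padding. There are no true dynamics in these data:
#' any apparent eigenvalue structure comes from trial-timing variability
#' alone.
#'
#' @param mean_erps list with `times` (ms) and `templates` (named list of
#'   `2 x length(times)` condition-mean matrices), sampled at the analysis
#'   rate.
#' @param jitter a [jitter_config()].
#' @param n_trials trials to generate.
#' @param age target age group (must be a name of `sigma_by_age`).
#' @param seed optional seed.
#' @param lock event lock label for the returned object.
#' @param condition_probs sampling probabilities over the template names.
#' @param recording recording metadata list.
#' @return a `latent_trials` object (`trials x 2 x time`).
#' @export
make_jittered_dataset <- function(mean_erps, jitter, n_trials, age,
                                  seed = NULL, lock = "stimulus",
                                  condition_probs = NULL,
                                  recording = list()) {
  stopifnot(inherits(jitter, "jitter_config"))
  key <- as.character(age)
  if (!key %in% names(jitter$sigma_by_age))
    stop_invalid(sprintf("age %s not in the sigma_by_age map (%s)",
                         key, paste(names(jitter$sigma_by_age), collapse = ", ")))
  sigma <- jitter$sigma_by_age[[key]]
  if (!is.null(seed)) set.seed(seed)
  tms <- mean_erps$times
  tpl <- mean_erps$templates
  conds <- sample(names(tpl), n_trials, replace = TRUE, prob = condition_probs)
  nt <- length(tms)
  fs <- 1000 / (tms[2] - tms[1])
  tau <- rnorm(n_trials, 0, sigma)
  v <- array(0, c(n_trials, 2, nt))
  dt <- tms[2] - tms[1]
  for (i in seq_len(n_trials)) {
    m <- tpl[[conds[i]]]
    # linear interpolation at t + tau with nearest-value edge padding
    f <- pmin(pmax((tms + tau[i] - tms[1]) / dt + 1, 1), nt)
    lo <- floor(f); hi <- pmin(lo + 1, nt); w <- f - lo
    v[i, 1, ] <- m[1, lo] * (1 - w) + m[1, hi] * w
    v[i, 2, ] <- m[2, lo] * (1 - w) + m[2, hi] * w
  }
  if (jitter$eps_sd > 0)
    v <- v + array(rnorm(length(v), 0, jitter$eps_sd), dim(v))
  trials <- tibble::tibble(trial = seq_len(n_trials), condition = conds,
                           rt_ms = NA_real_, responded = TRUE, tau_ms = tau)
  latent_trials(v, fs = fs, lock = lock, times = tms, trials = trials,
                recording = recording)
}

#' Condition-mean latent ERPs from the ground truth
#'
#' Convenience accessor used by the jitter control: the true templates on
#' the analysis grid of a lock window.
#'
#' @param truth a [ground_truth_dynamics()].
#' @param lock event lock.
#' @param fs analysis rate (Hz).
#' @param window `(start_ms, end_ms)`; defaults to the lock's analysis
#'   window.
#' @return list with `times` and `templates` as used by
#'   [make_jittered_dataset()].
#' @export
mean_erps_from_truth <- function(truth, lock, fs = 30, window = NULL) {
  win <- window %||% lock_windows()[[lock]]
  tms <- time_grid(win[1], win[2], fs)
  tpl <- lapply(setNames(condition_levels(), condition_levels()),
                function(cd) truth$erp_templates(lock, cd, tms))
  list(times = tms, templates = tpl)
}
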