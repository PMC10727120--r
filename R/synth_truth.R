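#' Longitudinal cohort configuration for the synthetic generator
#'
#' Defaults emulate the study design the pipeline targets: a flanker task
#' with 384 trials per session, recorded with 104 sensors at 250 Hz, at
#' three longitudinal waves with target ages 12, 15 and 18 years and
#' incomplete follow-up. The four conditions are flanker congruency crossed
#' with response outcome; their default probabilities reproduce typical
#' accuracies (congruent ~0.97, incongruent ~0.77).
#'
#' @param n_subjects number of participants.
#' @param waves target ages (years) of the longitudinal waves.
#' @param missingness probability that a subject skips a wave
#'   (independent Bernoulli per wave; `0 <= missingness < 1`).
#' @param n_trials trials per session.
#' @param n_sensors EEG sensors.
#' @param fs_raw acquisition sampling rate in Hz. Set to the analysis rate
#'   (30) to generate directly on the analysis grid and skip the filtering
#'   stage.
#' @param condition_probs probabilities of the four conditions in
#'   [condition_levels()] order; must sum to 1.
#' @param omission_prob probability of a no-response trial.
#' @param age_sd SD of true age around the wave target.
#' @param seed integer seed; the generator fans it out into per-subject
#'   substreams so subject subsets are reproducible.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 179, waves = c(12, 15, 18),
                          missingness = 0.24, n_trials = 384,
                          n_sensors = 104, fs_raw = 250,
                          condition_probs = c(0.485, 0.015, 0.385, 0.115),
                          omission_prob = 0.02, age_sd = 0.5, seed = 1) {
  if (!is_count(n_subjects) || !is_count(n_trials) || !is_count(n_sensors))
    stop_invalid("n_subjects, n_trials and n_sensors must be positive integers")
  if (!is.numeric(missingness) || missingness < 0 || missingness >= 1)
    stop_invalid("missingness must satisfy 0 <= missingness < 1")
  if (length(condition_probs) != 4 || !is_prob(condition_probs) ||
      abs(sum(condition_probs) - 1) > 1e-8)
    stop_invalid("condition_probs must be 4 probabilities summing to 1")
  if (!is.numeric(waves) || !length(waves)) stop_invalid("waves must be target ages")
  structure(
    list(n_subjects = as.integer(n_subjects), waves = as.numeric(waves),
         missingness = missingness, n_trials = as.integer(n_trials),
         n_sensors = as.integer(n_sensors), fs_raw = fs_raw,
         condition_probs = setNames(as.numeric(condition_probs), condition_levels()),
         omission_prob = omission_prob, age_sd = age_sd,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Ground-truth dynamics for the synthetic cohort
#'
#' Houses everything the generator needs to realize the forward model: the
#' 2x2 AR(1) dynamics matrix as a function of event lock, window time and
#' age; the rank-2 sensor mixing; the per-condition latent ERP templates;
#' the innovation SD; and the couplings that tie a session's eigenvalue to
#' its behavior.
#'
#' By default the dynamics matrix is diagonal with eigenvalues
#' `base_eigenvalues` at the reference age (15 years), an age gradient
#' applied only in the stimulus- and response-locked epochs (flat in the
#' cue epoch), and a per-subject random offset on the diagonal. The default
#' stimulus/response slope of -0.025 per year gives an eigenvalue drop of
#' 0.15 across ages 12-18.
#'
#' @param n_sensors sensors in the mixing matrix.
#' @param base_eigenvalues eigenvalues of A at the reference age.
#' @param age_slopes named list (`cue`, `stimulus`, `response`) of length-2
#'   eigenvalue-vs-age slopes (per year).
#' @param ref_age reference age in years.
#' @param subject_sd SD of the per-subject eigenvalue offset.
#' @param noise_sd innovation SD of the AR(1) residual process (z-units;
#'   with unit innovations the z-scored latent SD is of order 1).
#' @param sensor_noise_sd SD of white sensor noise added after mixing. The
#'   signal-to-noise ratio of real recordings is not something the analysis
#'   pins down, so this is a configuration choice.
#' @param erp_scale peak amplitude of the ERP templates in z-units of the
#'   single-trial fluctuation (single-trial EEG variability dominates the
#'   evoked response; 0.4 is a realistic evoked-to-residual ratio).
#' @param rt_coupling slope linking the session eigenvalue (z-scored across
#'   the cohort) to mean RT (z-scored), default 0.233.
#' @param acc_coupling accuracy decrease per SD of eigenvalue.
#' @param A_of_t optional `function(lock, t_ms, age)` returning a 2x2
#'   matrix, overriding the diagonal default. Must keep spectral radius
#'   below 1 for all ages/locks/times used.
#' @param sensor_loadings optional `n_sensors x 2` mixing matrix (rank 2);
#'   default [default_sensor_loadings()].
#' @param erp_templates optional `function(lock, condition, times_ms)`
#'   returning a `2 x length(times)` latent template; default
#'   [default_erp_templates()] scaled by `erp_scale`.
#' @param eig_pop_mean,eig_pop_sd population mean and SD used to z-score a
#'   session eigenvalue inside the behavior couplings.
#' @param rt_base_ms,rt_age_slope,rt_sd_ms,rt_trial_sd_ms RT model: session
#'   mean RT at the reference age, its decrease per year of age, the
#'   between-session RT SD, and the within-session trial RT SD.
#' @param acc_base,acc_age_slope,acc_noise_sd accuracy model.
#' @return a `ground_truth_dynamics` list.
#' @export
ground_truth_dynamics <- function(n_sensors = 104,
                                  base_eigenvalues = c(0.55, 0.35),
                                  age_slopes = list(cue = c(0, 0),
                                                    stimulus = c(-0.025, -0.025),
                                                    response = c(-0.025, -0.025)),
                                  ref_age = 15, subject_sd = 0.03,
                                  noise_sd = 1, sensor_noise_sd = 0.2,
                                  erp_scale = 0.4, rt_coupling = 0.233,
                                  acc_coupling = 0.02,
                                  A_of_t = NULL, sensor_loadings = NULL,
                                  erp_templates = NULL,
                                  eig_pop_mean = base_eigenvalues[2],
                                  eig_pop_sd = 0.065,
                                  rt_base_ms = 380, rt_age_slope = 8,
                                  rt_sd_ms = 45, rt_trial_sd_ms = 80,
                                  acc_base = 0.87, acc_age_slope = 0.012,
                                  acc_noise_sd = 0.03) {
  if (any(!is.finite(base_eigenvalues)) || any(base_eigenvalues < 0) ||
      any(base_eigenvalues >= 1))
    stop_invalid("base_eigenvalues must lie in [0, 1) (stability)")
  if (is.null(sensor_loadings)) sensor_loadings <- default_sensor_loadings(n_sensors)
  if (qr(sensor_loadings)$rank < 2)
    stop_invalid("sensor_loadings must have rank 2")
  if (is.null(erp_templates)) {
    scale_ <- erp_scale
    erp_templates <- function(lock, condition, times_ms)
      default_erp_templates(lock, condition, times_ms) * scale_
  }
  if (is.null(A_of_t)) {
    A_of_t <- function(lock, t_ms, age) {
      sl <- age_slopes[[lock]] %||% c(0, 0)
      diag(pmin(pmax(base_eigenvalues + sl * (age - ref_age), 0), 0.97))
    }
  }
  truth <- structure(
    list(A_of_t = A_of_t, sensor_loadings = sensor_loadings,
         erp_templates = erp_templates, noise_sd = noise_sd,
         sensor_noise_sd = sensor_noise_sd, subject_sd = subject_sd,
         rt_coupling = rt_coupling, acc_coupling = acc_coupling,
         eig_pop_mean = eig_pop_mean, eig_pop_sd = eig_pop_sd,
         rt_base_ms = rt_base_ms, rt_age_slope = rt_age_slope,
         rt_sd_ms = rt_sd_ms, rt_trial_sd_ms = rt_trial_sd_ms,
         acc_base = acc_base, acc_age_slope = acc_age_slope,
         acc_noise_sd = acc_noise_sd, ref_age = ref_age),
    class = "ground_truth_dynamics")
  check_truth_stability(truth)
  truth
}

check_truth_stability <- function(truth, ages = c(12, 15, 18, 19),
                                  windows = lock_windows()) {
  for (lk in names(windows)) {
    for (age in ages) {
      for (t_ms in seq(windows[[lk]][1], windows[[lk]][2], length.out = 5)) {
        A <- truth$A_of_t(lk, t_ms, age)
        if (!is.matrix(A) || any(dim(A) != 2) || !all(is.finite(A)))
          stop_invalid("A_of_t must return a finite 2x2 matrix")
        if (spectral_radius(A) >= 1)
          stop_invalid(sprintf(
            "unstable dynamics: spectral radius >= 1 at lock %s, t = %g, age %g",
            lk, t_ms, age))
      }
    }
  }
  invisible(truth)
}

#' Default rank-2 sensor topographies
#'
#' Component 1 is an anterior-posterior gradient, component 2 a central
#' focus; the pair is orthonormalized. These emulate the spatial structure
#' of the two dominant ERP components (a frontal/occipital gradient and a
#' central-parietal focus), not any specific montage.
#'
#' @param n_sensors number of sensors (>= 2).
#' @return `n_sensors x 2` orthonormal matrix.
#' @export
default_sensor_loadings <- function(n_sensors) {
  if (n_sensors < 2) stop_invalid("need at least 2 sensors")
  s <- seq(0, 1, length.out = n_sensors)
  l1 <- cos(pi * s)
  l2 <- exp(-((s - 0.5)^2) / (2 * 0.18^2))
  Q <- qr.Q(qr(cbind(l1, l2)))
  for (k in 1:2) Q[, k] <- Q[, k] * sign(Q[which.max(abs(Q[, k])), k])
  Q
}

#' Default latent ERP templates
#'
#' Sums of Gaussian-windowed deflections per condition and component, with
#' unit peak scale (the generator multiplies by its `erp_scale`):
#' component 1 carries an early negative stimulus-locked deflection,
#' component 2 a later deflection that separates commission errors from
#' correct responses, strongest after the response; cue-locked responses
#' are small. Morphology is configuration, not science — any smooth,
#' band-limited template exercises the pipeline identically.
#'
#' @param lock event lock.
#' @param condition one of [condition_levels()].
#' @param times_ms sample times in ms relative to the lock.
#' @return `2 x length(times_ms)` matrix of latent template values.
#' @export
default_erp_templates <- function(lock, condition, times_ms) {
  g <- function(mu, sdev) exp(-((times_ms - mu)^2) / (2 * sdev^2))
  err <- grepl("error$", condition)
  incong <- grepl("^incongruent", condition)
  lat <- if (incong) 30 else 0
  c1 <- switch(lock,
    cue = -0.35 * g(150, 60) + 0.2 * g(320, 90),
    stimulus = -1.0 * g(100 + lat, 45) + 0.55 * g(250 + lat, 80),
    response = -0.5 * g(0, 60) + 0.25 * g(200, 90))
  c2 <- switch(lock,
    cue = 0.25 * g(200, 80),
    stimulus = (0.6 + 0.3 * err) * g(350 + lat, 90),
    response = (if (err) 1.0 else 0.35) * g(80, 70) - 0.2 * g(-150, 80))
  rbind(c1, c2)
}
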