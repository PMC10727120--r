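# shared fixtures and independent oracles, all built in code

# simulate 2-D AR(1) residual trials on the 30 Hz grid with known dynamics
make_ar_residuals <- function(n_trials, n_time, A, noise_sd = 1, seed = 1,
                              x0 = NULL) {
  set.seed(seed)
  x <- array(0, c(n_trials, 2, n_time))
  x[, , 1] <- if (is.null(x0)) matrix(rnorm(2 * n_trials), n_trials, 2) else x0
  for (t in seq_len(n_time - 1))
    x[, , t + 1] <- x[, , t] %*% t(A) +
      matrix(rnorm(2 * n_trials, 0, noise_sd), n_trials, 2)
  residual_trials(x, fs = 30,
                  times = seq(0, by = 1000 / 30, length.out = n_time))
}

# brute-force least squares for the window AR fit: numerical minimization of
# sum || y - A x ||^2 over the 4 entries of A (independent of the closed form)
brute_force_ar_fit <- function(X, Y) {
  # conjugate-gradient minimization of sum || y_k - X' w ||^2 per output row,
  # using only matrix-vector products with X (never the normal equations)
  cg_row <- function(y) {
    w <- c(0, 0)
    r <- as.vector(X %*% (y - crossprod(X, w)))  # -(1/2) gradient
    p <- r
    for (it in 1:20) {
      if (sqrt(sum(r^2)) < 1e-14) break
      Hp <- as.vector(X %*% crossprod(X, p))
      alpha <- sum(r^2) / sum(p * Hp)
      w <- w + alpha * p
      r_new <- r - alpha * Hp
      beta <- sum(r_new^2) / sum(r^2)
      r <- r_new
      p <- r + beta * p
    }
    w
  }
  rbind(cg_row(Y[1, ]), cg_row(Y[2, ]))
}

# brute-force TFCE: explicit double loop over thresholds and, for each
# point, a scan outwards to find its contiguous suprathreshold run
brute_force_tfce <- function(x, E = 0.5, H = 2, dh) {
  x[!is.finite(x)] <- 0
  n <- length(x)
  score <- numeric(n)
  mx <- max(x)
  if (mx <= 0) return(score)
  h <- dh
  while (h <= mx + 1e-12) {
    for (p in seq_len(n)) {
      if (x[p] >= h - 1e-12) {
        lo <- p
        while (lo > 1 && x[lo - 1] >= h - 1e-12) lo <- lo - 1
        hi <- p
        while (hi < n && x[hi + 1] >= h - 1e-12) hi <- hi + 1
        score[p] <- score[p] + (hi - lo + 1)^E * h^H * dh
      }
    }
    h <- h + dh
  }
  score
}

# small epoched dataset built from a known rank-2 forward model
make_rank2_epochs <- function(n_trials = 12, n_sensors = 6, n_time = 16,
                              fs = 30, lock = "stimulus", seed = 1,
                              loadings = NULL, noise_sd = 0) {
  set.seed(seed)
  if (is.null(loadings)) loadings <- default_sensor_loadings(n_sensors)
  lat <- array(rnorm(n_trials * 2 * n_time), c(n_trials, 2, n_time))
  dat <- array(0, c(n_trials, n_sensors, n_time))
  for (i in seq_len(n_trials))
    dat[i, , ] <- loadings %*% lat[i, , ] +
      matrix(rnorm(n_sensors * n_time, 0, noise_sd), n_sensors, n_time)
  trials <- tibble::tibble(
    condition = rep(condition_levels(), length.out = n_trials),
    rt_ms = runif(n_trials, 250, 600), responded = TRUE)
  list(epochs = eeg_epochs(dat, fs = fs, lock = lock,
                           times = seq(0, by = 1000 / fs, length.out = n_time),
                           trials = trials,
                           recording = list(recording_id = "R1",
                                            participant = "P1", age = 15,
                                            sex = "F", wave = 2)),
       latent = lat, loadings = loadings)
}

# longitudinal eigenvalue-style table with a known fixed effect and random
# intercepts, for mixed-model tests
make_lmm_table <- function(n_subjects = 60, n_waves = 3, n_windows = 5,
                           beta_age = 0, intercept_sd = 0.05,
                           resid_sd = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    u <- rnorm(1, 0, intercept_sd)
    for (w in seq_len(n_waves)) {
      age <- c(12, 15, 18)[w] + rnorm(1, 0, 0.5)
      y <- 0.5 + beta_age * age + u + rnorm(n_windows, 0, resid_sd)
      rows[[length(rows) + 1]] <- tibble::tibble(
        recording_id = sprintf("S%03d_w%d", i, w),
        participant = sprintf("P%03d", i), age = age,
        window_ms = seq(0, by = 100 / 3, length.out = n_windows),
        eig1 = y)
    }
  }
  dplyr::bind_rows(rows)
}

tiny_cohort <- function(n_subjects = 6, n_trials = 24, n_sensors = 6,
                        fs_raw = 30, seed = 7, ...) {
  cc <- cohort_config(n_subjects = n_subjects, n_trials = n_trials,
                      n_sensors = n_sensors, fs_raw = fs_raw, seed = seed,
                      missingness = 0.2)
  tr <- ground_truth_dynamics(n_sensors = n_sensors, ...)
  simulate_cohort(cc, tr)
}
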