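test_that("simulation is deterministic given the seed and subject substreams are stable", {
  cc <- cohort_config(n_subjects = 3, n_trials = 16, n_sensors = 4,
                      fs_raw = 30, seed = 42, missingness = 0.2)
  tr <- ground_truth_dynamics(n_sensors = 4)
  a <- simulate_cohort(cc, tr, locks = c("stimulus", "response"))
  b <- simulate_cohort(cc, tr, locks = c("stimulus", "response"))
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$recording_id, b$recording_id)
  expect_identical(a$truth_eig2, b$truth_eig2)

  # per-subject substreams: adding subjects leaves earlier subjects unchanged
  cc5 <- cohort_config(n_subjects = 5, n_trials = 16, n_sensors = 4,
                       fs_raw = 30, seed = 42, missingness = 0.2)
  c5 <- simulate_cohort(cc5, tr, locks = c("stimulus", "response"))
  shared <- intersect(a$recording_id, c5$recording_id)
  expect_identical(shared, a$recording_id)
  for (rid in shared)
    expect_identical(a$epochs[[match(rid, a$recording_id)]],
                     c5$epochs[[match(rid, c5$recording_id)]])
})

test_that("with zero innovations and zero sensor noise trials equal their condition template", {
  cc <- cohort_config(n_subjects = 2, n_trials = 8, n_sensors = 5,
                      fs_raw = 30, seed = 1, missingness = 0, omission_prob = 0)
  tr <- ground_truth_dynamics(n_sensors = 5, noise_sd = 0,
                              sensor_noise_sd = 0, subject_sd = 0)
  co <- simulate_cohort(cc, tr, locks = "stimulus")
  e <- co$epochs[[1]]$stimulus
  for (i in seq_len(nrow(e$trials))) {
    tpl <- tr$erp_templates("stimulus", e$trials$condition[i], e$times)
    expect_equal(e$data[i, , ], tr$sensor_loadings %*% tpl,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("generator rejects unstable dynamics and rank-deficient loadings", {
  expect_error(ground_truth_dynamics(n_sensors = 4,
                                     base_eigenvalues = c(1.05, 0.4)),
               class = "eegdyn_invalid")
  L <- cbind(rep(1, 6), rep(2, 6))  # rank 1
  expect_error(ground_truth_dynamics(n_sensors = 6, sensor_loadings = L),
               class = "eegdyn_invalid")
  A_bad <- function(lock, t_ms, age) diag(c(1.2, 0.5))
  expect_error(ground_truth_dynamics(n_sensors = 4, A_of_t = A_bad),
               class = "eegdyn_invalid")
})

test_that("cohort config invariants are enforced", {
  expect_error(cohort_config(missingness = 1), class = "eegdyn_invalid")
  expect_error(cohort_config(n_trials = 0), class = "eegdyn_invalid")
  expect_error(cohort_config(condition_probs = c(0.5, 0.5, 0.2, 0.2)),
               class = "eegdyn_invalid")
  expect_silent(cohort_config(n_subjects = 2))
})

test_that("behavior couples RT to the eigenvalue at the configured slope", {
  tr <- ground_truth_dynamics(n_sensors = 4)
  expect_error(simulate_behavior(tr, 1.2, 15), class = "eegdyn_invalid")

  # zero coupling: RT independent of the eigenvalue
  tr0 <- ground_truth_dynamics(n_sensors = 4, rt_coupling = 0)
  set.seed(11)
  eig <- pmin(pmax(rnorm(400, tr0$eig_pop_mean, tr0$eig_pop_sd), 0), 0.9)
  rt0 <- vapply(eig, function(e) simulate_behavior(tr0, e, 15)$mean_rt, 0)
  expect_lt(abs(cor(eig, rt0)), 0.12)

  # default coupling: standardized regression slope recovers 0.233
  set.seed(12)
  rt <- vapply(eig, function(e) simulate_behavior(tr, e, 15)$mean_rt, 0)
  fit <- lm(scale(rt) ~ scale(eig))
  ci <- confint(fit)[2, ]
  expect_gt(0.233, ci[1] - 1e-9)
  expect_lt(0.233, ci[2] + 1e-9)

  # accuracy stays within [0, 1] even under extreme couplings
  tr_neg <- ground_truth_dynamics(n_sensors = 4, acc_coupling = -5)
  accs <- vapply(seq(0, 0.9, by = 0.1), function(e)
    simulate_behavior(tr_neg, e, 15, seed = 1)$accuracy, 0)
  expect_true(all(accs <= 1 & accs >= 0))
})

test_that("jittered datasets implement the shifted-template model", {
  tr <- ground_truth_dynamics(n_sensors = 4)
  erps <- mean_erps_from_truth(tr, "stimulus")

  # zero jitter and zero noise: every trial equals its condition mean
  j0 <- jitter_config(sigma_by_age = c("12" = 0), eps_sd = 0)
  lat <- make_jittered_dataset(erps, j0, n_trials = 6, age = 12, seed = 1)
  for (i in 1:6)
    expect_equal(lat$values[i, , ], erps$templates[[lat$trials$condition[i]]],
                 tolerance = 1e-12, ignore_attr = TRUE)

  # age-group lookup and the 97 ms SD for the youngest group
  jc <- jitter_config()
  expect_error(make_jittered_dataset(erps, jc, 5, age = 14),
               class = "eegdyn_invalid")
  lat12 <- make_jittered_dataset(erps, jc, n_trials = 10000, age = 12, seed = 2)
  expect_lt(abs(sd(lat12$trials$tau_ms) - 97) / 97, 0.03)

  # shifts use nearest-value edge padding
  jbig <- jitter_config(sigma_by_age = c("12" = 5000), eps_sd = 0)
  latb <- make_jittered_dataset(erps, jbig, n_trials = 4, age = 12, seed = 3)
  i <- which.max(abs(latb$trials$tau_ms))
  tpl <- erps$templates[[latb$trials$condition[i]]]
  edge <- if (latb$trials$tau_ms[i] > 0) ncol(tpl) else 1
  expect_equal(latb$values[i, , ncol(tpl) / 2],
               tpl[, edge], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("simulated residual variance stays bounded for shipped configs", {
  co <- tiny_cohort(n_subjects = 3, n_trials = 24, seed = 5)
  for (r in seq_len(nrow(co))) {
    for (lk in names(co$epochs[[r]])) {
      e <- co$epochs[[r]][[lk]]
      expect_true(all(is.finite(e$data)))
      expect_lt(max(abs(e$data)), 50)
    }
  }
})
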