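test_that("component space recovers a rank-2 forward model", {
  set.seed(4)
  L <- default_sensor_loadings(8)
  tpl <- lapply(1:4, function(j) matrix(rnorm(2 * 20), 2, 20))
  ga <- lapply(tpl, function(m) L %*% m)
  names(ga) <- paste0("stimulus.", condition_levels())
  sp <- fit_component_space(ga)
  expect_gte(sum(sp$explained_fraction), 0.999)
  expect_true(sp$explained_fraction[1] >= sp$explained_fraction[2])
  # orthonormal columns
  expect_equal(crossprod(sp$loadings), diag(2), tolerance = 1e-10)
  # loadings span the true mixing space
  proj <- L %*% solve(crossprod(L), crossprod(L, sp$loadings))
  expect_equal(proj, sp$loadings, tolerance = 1e-8)
})

test_that("sensor permutation permutes loading rows identically", {
  set.seed(5)
  ga <- list(a = matrix(rnorm(6 * 30), 6, 30), b = matrix(rnorm(6 * 30), 6, 30))
  sp <- fit_component_space(ga)
  perm <- c(4, 2, 6, 1, 3, 5)
  sp_p <- fit_component_space(lapply(ga, function(m) m[perm, ]))
  expect_equal(sp_p$loadings, sp$loadings[perm, ], tolerance = 1e-10)
  expect_equal(sp_p$explained_fraction, sp$explained_fraction, tolerance = 1e-12)
})

test_that("degenerate grand averages are refused", {
  ga <- list(a = matrix(rep(1:6, 10), 6, 10))  # rank 1 after centering
  expect_error(fit_component_space(ga), class = "eegdyn_invalid")
  expect_error(fit_component_space(list(a = matrix(1, 6, 1))),
               class = "eegdyn_invalid")
})

test_that("projection + z-scoring standardizes per subject and is scale invariant", {
  fx <- make_rank2_epochs(n_trials = 10, n_sensors = 6, n_time = 20, seed = 6)
  sp <- fit_component_space(list(m = fx$loadings %*% matrix(rnorm(2 * 40), 2, 40)))
  lat <- project_and_zscore(fx$epochs, sp)
  for (k in 1:2) {
    pooled <- as.vector(lat$values[, k, ])
    expect_lt(abs(mean(pooled)), 1e-10)
    expect_lt(abs(sqrt(mean((pooled - mean(pooled))^2)) - 1), 1e-10)
  }
  # doubling raw amplitudes leaves the z-scored output unchanged
  doubled <- fx$epochs
  doubled$data <- doubled$data * 2
  lat2 <- project_and_zscore(doubled, sp)
  expect_equal(lat2$values, lat$values, tolerance = 1e-12)
})

test_that("projection recovers known latent series up to sign and scale", {
  fx <- make_rank2_epochs(n_trials = 8, n_sensors = 10, n_time = 25,
                          seed = 7, noise_sd = 0)
  # fit the space on templates whose two rows are orthogonal with distinct
  # variances, so the principal axes align with the generating components
  tt <- (0:59) / 60
  tpl <- rbind(3 * sin(2 * pi * 3 * tt), 1 * cos(2 * pi * 7 * tt))
  sp <- fit_component_space(list(m = fx$loadings %*% tpl))
  lat <- project_and_zscore(fx$epochs, sp)
  for (k in 1:2) {
    truth <- as.vector(fx$latent[, k, ])
    est <- as.vector(lat$values[, k, ])
    expect_gt(abs(cor(truth, est)), 0.999)
  }
})

test_that("a flat component is a hard error naming the component", {
  fx <- make_rank2_epochs(n_trials = 4, n_sensors = 6, n_time = 10, seed = 8)
  sp <- fit_component_space(list(m = fx$loadings %*% matrix(rnorm(2 * 30), 2, 30)))
  flat <- fx$epochs
  flat$data[] <- 0
  expect_error(project_and_zscore(flat, sp), regexp = "component",
               class = "eegdyn_numerical")
})

test_that("z-score params are pooled across locks supplied together", {
  fx1 <- make_rank2_epochs(seed = 9, lock = "stimulus")
  fx2 <- make_rank2_epochs(seed = 10, lock = "response")
  sp <- fit_component_space(list(m = fx1$loadings %*% matrix(rnorm(2 * 40), 2, 40)))
  lats <- project_and_zscore(list(stimulus = fx1$epochs, response = fx2$epochs), sp)
  expect_identical(lats$stimulus$zscore_params, lats$response$zscore_params)
  pooled <- c(as.vector(lats$stimulus$values[, 1, ]),
              as.vector(lats$response$values[, 1, ]))
  expect_lt(abs(mean(pooled)), 1e-10)
  # per-lock alone the mean need not vanish (single session-wide standardization)
  expect_gt(abs(mean(lats$stimulus$values[, 1, ])), 1e-10)
})
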