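test_that("condition-mean residuals are exact", {
  v <- array(0, c(3, 2, 2))
  v[1, , ] <- 1; v[2, , ] <- 3  # two trials of one condition: a = 1, b = 3
  v[3, , ] <- 5                 # single-trial condition
  lat <- latent_trials(v, fs = 30, lock = "stimulus",
                       times = c(0, 1000 / 30),
                       trials = tibble::tibble(
                         condition = c("congruent_correct", "congruent_correct",
                                       "incongruent_error"),
                         rt_ms = 300, responded = TRUE),
                       recording = list())
  res <- compute_residuals(lat)
  expect_equal(res$values[1, , ], matrix(-1, 2, 2))  # a - (a+b)/2
  expect_equal(res$values[2, , ], matrix(1, 2, 2))   # b - (a+b)/2
  expect_equal(res$values[3, , ], matrix(0, 2, 2))   # single trial -> zero
  expect_equal(res$trials$excluded_from_fit, c(FALSE, FALSE, TRUE))
  # per-condition per-timepoint residual means vanish
  set.seed(1)
  v2 <- array(rnorm(40), c(10, 2, 2))
  lat2 <- latent_trials(v2, fs = 30, lock = "cue", times = c(0, 1000 / 30),
                        trials = tibble::tibble(
                          condition = rep(condition_levels()[1:2], 5),
                          rt_ms = 300, responded = TRUE),
                        recording = list())
  r2 <- compute_residuals(lat2)
  for (cd in unique(lat2$trials$condition)) {
    i <- lat2$trials$condition == cd
    expect_lt(max(abs(apply(r2$values[i, , , drop = FALSE], c(2, 3), mean))), 1e-12)
  }
})

test_that("noiseless linear trials are fit exactly", {
  A <- 0.5 * diag(2)
  res <- make_ar_residuals(6, 10, A, noise_sd = 0, seed = 2)
  fit <- fit_window_ar1(res, window_center = res$times[5])
  expect_equal(fit$A_hat, A, tolerance = 1e-12)
  expect_equal(fit$n_pairs, 12)
})

test_that("closed-form window fit equals brute-force least squares", {
  set.seed(3)
  for (rep in 1:25) {
    res <- make_ar_residuals(5, 3, matrix(runif(4, -0.4, 0.8), 2, 2) * 0.6,
                             seed = rep)
    fit <- fit_window_ar1(res, window_center = res$times[2])
    v <- res$values
    X <- rbind(as.vector(v[, 1, 1:2]), as.vector(v[, 2, 1:2]))
    Y <- rbind(as.vector(v[, 1, 2:3]), as.vector(v[, 2, 2:3]))
    expect_equal(fit$A_hat, brute_force_ar_fit(X, Y), tolerance = 1e-8)
  }
})

test_that("windows below the pair minimum are skipped, not fabricated", {
  res <- make_ar_residuals(1, 10, 0.5 * diag(2), seed = 4)
  fit <- suppressMessages(fit_window_ar1(res, res$times[5], min_pairs = 4))
  expect_true(all(is.na(fit$A_hat)))
  expect_equal(fit$n_pairs, 2)
})

test_that("eigenvalue ordering follows component association", {
  # diagonal: slot k carries A[k,k], coordinate-axis vectors
  eo <- order_eigs(diag(c(0.7, 0.3)))
  expect_equal(eo$moduli, c(0.7, 0.3))
  expect_equal(eo$vectors, diag(2))
  expect_false(eo$complex)

  # eigenvectors associated crosswise: labels swap
  V <- cbind(c(0.2, 0.98), c(0.98, 0.2))
  A <- V %*% diag(c(0.8, 0.3)) %*% solve(V)
  eo2 <- order_eigs(A)
  expect_equal(eo2$moduli, c(0.3, 0.8), tolerance = 1e-10)
  expect_gt(abs(eo2$vectors[1, 1]), abs(eo2$vectors[2, 1]))

  # rotation-like matrix: complex pair, both moduli equal r
  r <- 0.6; th <- 0.8
  R <- r * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  eo3 <- order_eigs(R)
  expect_true(eo3$complex)
  expect_equal(eo3$moduli, c(r, r), tolerance = 1e-12)

  # closed-form 2x2 eigen agrees with LAPACK
  set.seed(5)
  for (i in 1:50) {
    A <- matrix(rnorm(4), 2, 2)
    ev <- eigen(A, only.values = TRUE)$values
    expect_equal(sort(Mod(order_eigs(A)$values)), sort(Mod(ev)),
                 tolerance = 1e-10)
  }
})

test_that("sweep matches the single-window reference fit everywhere", {
  set.seed(6)
  res <- make_ar_residuals(20, 14, matrix(c(0.6, 0.1, -0.1, 0.4), 2, 2),
                           seed = 6)
  sw <- sweep_dynamics(res)
  expect_equal(nrow(sw), 12)
  expect_true(all(sw$n_pairs == 40))  # 3 samples/window -> 2 pairs/trial
  for (w in c(1, 5, 12)) {
    fit <- fit_window_ar1(res, sw$window_ms[w])
    eo <- order_eigs(fit$A_hat)
    expect_equal(c(sw$a11[w], sw$a12[w], sw$a21[w], sw$a22[w]),
                 as.vector(t(fit$A_hat)), tolerance = 1e-12)
    expect_equal(c(sw$eig1[w], sw$eig2[w]), eo$moduli, tolerance = 1e-12)
    expect_equal(sw$complex[w], eo$complex)
  }
  # step = window width gives non-overlapping windows, count = floor(T/3)
  sw3 <- sweep_dynamics(res, step_samples = 3)
  expect_equal(nrow(sw3), floor(14 / 3))
})

test_that("a constant generating matrix yields a flat eigenvalue time course", {
  res <- make_ar_residuals(300, 31, diag(c(0.6, 0.35)), seed = 7)
  sw <- sweep_dynamics(res)
  expect_lt(diff(range(sw$eig1)), 0.2)
  expect_lt(abs(mean(sw$eig1) - 0.6), 0.04)
  expect_lt(abs(mean(sw$eig2) - 0.35), 0.04)
})

test_that("larger generating coefficients yield larger estimated moduli", {
  grid <- seq(0.1, 0.9, by = 0.1)
  est <- vapply(seq_along(grid), function(i) {
    res <- make_ar_residuals(150, 7, diag(rep(grid[i], 2)), seed = 100 + i)
    mean(sweep_dynamics(res)$eig1)
  }, 0)
  expect_equal(cor(grid, est, method = "spearman"), 1)
})

test_that("all-zero residuals are a numerical error, not a silent zero", {
  res <- make_ar_residuals(10, 8, 0.5 * diag(2), noise_sd = 0, seed = 8,
                           x0 = matrix(0, 10, 2))
  expect_error(sweep_dynamics(res), class = "eegdyn_numerical")
})
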