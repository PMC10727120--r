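test_that("compiled REML matches lme4::lmer t statistics", {
  skip_if_not_installed("lme4")
  tbl <- make_lmm_table(n_subjects = 40, beta_age = -0.01,
                        intercept_sd = 0.05, resid_sd = 0.05, seed = 2)
  fast <- lmm_timecourse(tbl, outcome = "eig1", predictor = "age",
                         engine = "reml")
  ref <- lmm_timecourse(tbl, outcome = "eig1", predictor = "age",
                        engine = "lme4")
  expect_equal(fast$t, ref$t, tolerance = 1e-4)
  expect_equal(fast$estimate, ref$estimate, tolerance = 1e-5)
})

test_that("with one observation per participant the LMM collapses to OLS", {
  set.seed(3)
  n <- 50
  tbl <- tibble::tibble(
    recording_id = sprintf("R%02d", 1:n),
    participant = sprintf("P%02d", 1:n),  # no repeated measures
    age = runif(n, 12, 18),
    window_ms = 0,
    eig1 = 0.5 - 0.01 * runif(n, 12, 18) + rnorm(n, 0, 0.05))
  fast <- lmm_timecourse(tbl, outcome = "eig1", predictor = "age")
  ols <- summary(lm(eig1 ~ age, data = tbl))$coefficients
  expect_equal(fast$t, ols["age", "t value"], tolerance = 1e-6)
})

test_that("LMM recovers a known longitudinal fixed effect", {
  hits <- 0
  for (s in 1:25) {
    tbl <- make_lmm_table(n_subjects = 150, beta_age = -0.02,
                          intercept_sd = 0.05, resid_sd = 0.05,
                          n_windows = 1, seed = s)
    f <- lmm_timecourse(tbl, outcome = "eig1", predictor = "age")
    ci <- f$estimate + c(-1.96, 1.96) * f$se
    if (ci[1] <= -0.02 && -0.02 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 22)  # ~95% coverage, allow binomial slack
})

test_that("a permuted predictor gives nominal-level window-wise t statistics", {
  # windows sharing one permuted predictor are correlated, so the rate is
  # averaged over several independent permutations
  set.seed(4)
  exceed <- 0; total <- 0
  for (s in 1:6) {
    tbl <- make_lmm_table(n_subjects = 50, beta_age = -0.03, n_windows = 30,
                          seed = s)
    recs <- unique(tbl$recording_id)
    perm <- setNames(sample(tbl$age[match(recs, tbl$recording_id)]), recs)
    tbl$age <- perm[tbl$recording_id]
    f <- lmm_timecourse(tbl, outcome = "eig1", predictor = "age")
    exceed <- exceed + sum(abs(f$t) > 1.96)
    total <- total + nrow(f)
  }
  rate <- exceed / total
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.15)
})

test_that("TFCE matches its closed form and brute-force oracle", {
  # no suprathreshold mass
  expect_equal(tfce_1d(rep(0, 20)), rep(0, 20))
  expect_equal(tfce_1d(c(-3, -1, 0, -2)), rep(0, 4))

  # isolated unit-extent peak: score -> h^3/3 as dh -> 0 (E=0.5, H=2)
  h0 <- 1.7
  x <- c(0, 0, h0, 0, 0)
  fine <- tfce_1d(x, nsteps = 20000)[3]
  expect_lt(abs(fine - h0^3 / 3) / (h0^3 / 3), 1e-3)

  # brute-force double loop over thresholds and runs, random series
  set.seed(5)
  for (rep in 1:10) {
    x <- pmax(rnorm(50, 0.5, 1), 0) * sample(c(1, 1, 1, 0), 50, replace = TRUE)
    dh <- max(x) / 100
    expect_equal(tfce_1d(x, dh = dh), brute_force_tfce(x, dh = dh),
                 tolerance = 1e-6)
  }

  # C++ path used in the bootstrap is the same algorithm
  set.seed(6)
  x <- abs(rnorm(50))
  expect_equal(tfce_1d(x),
               as.numeric(eegdynamics:::tfce_1d_cpp(x)), tolerance = 1e-12)

  expect_error(tfce_1d(c(1, 2), dh = 0), class = "eegdyn_invalid")
})

test_that("TFCE is monotone: raising a value never lowers any score", {
  set.seed(7)
  x <- pmax(rnorm(30, 0.3), 0)
  s0 <- tfce_1d(x, dh = 0.01)
  for (i in c(3, 15, 28)) {
    x2 <- x
    x2[i] <- x2[i] + 0.5
    s2 <- tfce_1d(x2, dh = 0.01)
    expect_true(all(s2 >= s0 - 1e-12))
  }
})

test_that("family-wise alpha follows the Bonferroni rule", {
  expect_equal(round(correct_family(0.05, 6), 4), 0.0083)
  expect_equal(correct_family(0.05, 18), 0.05 / 18)
  expect_equal(floor(correct_family(0.05, 18) * 1e4) / 1e4, 0.0027)
  expect_equal(correct_family(0.05, 1), 0.05)
  expect_error(correct_family(0.05, 0), class = "eegdyn_invalid")
})

test_that("cluster test is seed-deterministic and honors the add-one convention", {
  tbl <- make_lmm_table(n_subjects = 25, beta_age = -0.03, n_windows = 12,
                        seed = 8)
  ct1 <- cluster_test(tbl, "eig1", "age", tail = "negative", reps = 200,
                      n_tests = 6, seed = 99)
  ct2 <- cluster_test(tbl, "eig1", "age", tail = "negative", reps = 200,
                      n_tests = 6, seed = 99)
  expect_identical(ct1$windows, ct2$windows)
  expect_identical(ct1$null_max, ct2$null_max)

  # testing the wrong tail: oriented series all negative -> tfce 0 -> p = 1
  ct_wrong <- cluster_test(tbl, "eig1", "age", tail = "positive", reps = 200,
                           n_tests = 6, seed = 100)
  zero <- ct_wrong$windows$tfce == 0
  expect_true(all(ct_wrong$windows$p[zero] == 1))
  expect_true(min(ct1$windows$p) >= 1 / 201)

  # Bonferroni dominance: corrected-significant windows are a subset of
  # uncorrected-significant ones
  expect_true(all(ct1$windows$p[ct1$windows$sig] <= 0.05 / 6))
  expect_true(all(ct1$windows$p[ct1$windows$sig] <= 0.05))

  # a strong within-subject effect is detected
  expect_true(any(ct1$windows$sig))

  # tidy/glance accessors
  expect_identical(generics::tidy(ct1), ct1$windows)
  g <- generics::glance(ct1)
  expect_equal(g$n_windows, 12)
  expect_equal(g$alpha_corrected, 0.05 / 6)
})

test_that("specialized p = 2 bootstrap fitter agrees with the generic REML", {
  set.seed(10)
  for (rep in 1:10) {
    G <- 20
    g <- as.integer(rep(0:(G - 1), each = 3))
    n <- length(g)
    x <- rnorm(n)
    u <- rnorm(G, 0, runif(1, 0, 0.3))
    y <- 0.4 - 0.2 * x + u[g + 1] + rnorm(n, 0, 0.4)
    t_p2 <- eegdynamics:::lmm_t_p2_cpp(y, x, g, G, tol = 1e-8)
    t_gen <- eegdynamics:::reml_ri_cpp(y, cbind(1, x), g, G, tol = 1e-8)$t[2]
    expect_equal(t_p2, t_gen, tolerance = 1e-6)
  }
})

test_that("permutation variant runs and differs only in resampling scheme", {
  tbl <- make_lmm_table(n_subjects = 20, beta_age = 0, n_windows = 8, seed = 12)
  ct <- cluster_test(tbl, "eig1", "age", tail = "negative", reps = 150,
                     seed = 5, method = "permutation")
  expect_equal(length(ct$null_max), 150)
  expect_true(all(is.finite(ct$null_max)))
  expect_equal(ct$spec$method, "permutation")
})

test_that("covariates are supported (sex tests adjust for age)", {
  set.seed(13)
  tbl <- make_lmm_table(n_subjects = 40, beta_age = -0.02, n_windows = 6,
                        seed = 13)
  sex_by_p <- setNames(sample(c(0, 1), 40, TRUE),
                       sprintf("P%03d", 1:40))
  tbl$sex <- sex_by_p[tbl$participant]
  f <- lmm_timecourse(tbl, outcome = "eig1", predictor = "sex",
                      covariates = "age")
  expect_true(all(is.finite(f$t)))
  f_ref <- lmm_timecourse(tbl, outcome = "eig1", predictor = "sex",
                          covariates = "age", engine = "lme4")
  expect_equal(f$t, f_ref$t, tolerance = 1e-4)
})

test_that("behavior tables summarize accuracy and RT per recording", {
  trials <- tibble::tibble(
    recording_id = rep(c("A", "B"), each = 4),
    participant = rep(c("P1", "P2"), each = 4),
    age = rep(c(12, 15), each = 4),
    sex = "F", wave = 1,
    condition = c(rep("congruent_correct", 4),
                  "congruent_correct", "congruent_error",
                  "incongruent_correct", "incongruent_error"),
    rt_ms = c(rep(400, 4), 300, 350, 420, 500),
    responded = TRUE)
  bt <- behavior_tables(trials)
  expect_equal(bt$accuracy[bt$recording_id == "A"], 1)
  expect_equal(bt$rt_sd[bt$recording_id == "A"], 0)
  expect_equal(bt$accuracy[bt$recording_id == "B"], 0.5)
  expect_equal(bt$rt_mean_congruent[bt$recording_id == "B"], 325)

  # cohort-level: accuracy increasing with age is detected by the LMM
  co <- tiny_cohort(n_subjects = 12, n_trials = 40, seed = 20)
  tr_all <- dplyr::bind_rows(lapply(seq_len(nrow(co)), function(r)
    dplyr::mutate(co$epochs[[r]]$stimulus$trials,
                  recording_id = co$recording_id[r],
                  participant = co$participant[r],
                  age = co$age[r], sex = co$sex[r], wave = co$wave[r])))
  bt2 <- behavior_tables(tr_all)
  bt2$window_ms <- 0
  f <- lmm_timecourse(bt2, outcome = "accuracy", predictor = "age")
  expect_gt(f$t, 0)
})
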