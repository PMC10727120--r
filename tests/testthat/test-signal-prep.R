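make_tone_epochs <- function(freq, fs = 250, dur_ms = c(-600, 600), amp = 1) {
  tms <- time_grid(dur_ms[1], dur_ms[2], fs)
  v <- amp * sin(2 * pi * freq * tms / 1000)
  dat <- array(rep(v, each = 2), c(1, 2, length(tms)))
  eeg_epochs(dat, fs = fs, lock = "stimulus", times = tms,
             trials = tibble::tibble(condition = "congruent_correct",
                                     rt_ms = 400, responded = TRUE),
             recording = list(recording_id = "R", participant = "P",
                              age = 15, sex = "F", wave = 1))
}

sine_amplitude <- function(x, tms, freq) {
  X <- cbind(sin(2 * pi * freq * tms / 1000), cos(2 * pi * freq * tms / 1000))
  sqrt(sum(lm.fit(X, x)$coefficients^2))
}

test_that("lowpass passes DC and low frequencies, attenuates the stopband", {
  # DC: passband identity
  dc <- make_tone_epochs(0, amp = 0)
  dc$data[] <- 3.7
  out <- lowpass_downsample(dc)
  expect_equal(out$fs, 30)
  expect_equal(as.vector(out$data), rep(3.7, length(out$data)), tolerance = 1e-5)

  # 2 Hz: amplitude preserved within 2 percent (designed-response oracle)
  e2 <- make_tone_epochs(2)
  o2 <- lowpass_downsample(e2)
  mid <- abs(o2$times) <= 400  # avoid edge transients
  amp2 <- sine_amplitude(o2$data[1, 1, mid], o2$times[mid], 2)
  expect_gt(lowpass_response(2, fs = 250), 0.98)
  expect_lt(abs(amp2 - 1), 0.02)

  # 25 Hz: attenuated at least as strongly as the designed stopband gain
  e25 <- make_tone_epochs(25)
  o25 <- lowpass_downsample(e25)
  g25 <- lowpass_response(25, fs = 250)
  expect_lt(g25, 0.05)
  expect_lt(max(abs(o25$data[1, 1, abs(o25$times) <= 400])), g25 + 0.02)

  # metadata preserved
  expect_identical(o2$trials, e2$trials)
  expect_identical(o2$recording, e2$recording)
})

test_that("lowpass rejects cutoffs at or above Nyquist", {
  e <- make_tone_epochs(2, fs = 30)
  expect_error(lowpass_downsample(e, cutoff = 15, target_fs = 30),
               class = "eegdyn_invalid")
})

test_that("filtering is per-trial: no cross-trial leakage and order invariance", {
  set.seed(3)
  tms <- time_grid(-600, 600, 250)
  dat <- array(rnorm(3 * 2 * length(tms)), c(3, 2, length(tms)))
  mk <- function(d) eeg_epochs(
    d, fs = 250, lock = "stimulus", times = tms,
    trials = tibble::tibble(condition = rep("congruent_correct", dim(d)[1]),
                            rt_ms = 400, responded = TRUE),
    recording = list(recording_id = "R", participant = "P", age = 15,
                     sex = "F", wave = 1))
  all3 <- lowpass_downsample(mk(dat))
  one <- lowpass_downsample(mk(dat[2, , , drop = FALSE]))
  expect_equal(all3$data[2, , ], one$data[1, , ], tolerance = 1e-12)
  perm <- lowpass_downsample(mk(dat[c(3, 1, 2), , ]))
  expect_equal(perm$data[2, , ], all3$data[1, , ], tolerance = 1e-12)
})

test_that("segmentation gives inclusive-endpoint sample counts and drops omissions", {
  fs <- 30
  tms <- time_grid(-700, 700, fs)
  n <- 5
  dat <- array(rnorm(n * 2 * length(tms)), c(n, 2, length(tms)))
  trials <- tibble::tibble(
    condition = rep("incongruent_error", n),
    rt_ms = c(300, NA, 350, 400, 420),
    responded = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  e <- eeg_epochs(dat, fs = fs, lock = "response", times = tms,
                  trials = trials,
                  recording = list(recording_id = "R", participant = "P",
                                   age = 15, sex = "M", wave = 1))
  seg <- suppressMessages(segment_epochs(e))
  expect_equal(dim(seg$data)[3], 31)  # (-500..500) ms at 30 Hz
  expect_equal(dim(seg$data)[1], 4)   # omission dropped
  expect_equal(range(seg$times), c(-500, 500))
  # all three lock windows share the 33.33 ms grid
  for (lk in names(lock_windows())) {
    n_lk <- round(diff(lock_windows()[[lk]]) / 1000 * 30) + 1
    expect_equal(n_lk, length(time_grid(lock_windows()[[lk]][1],
                                        lock_windows()[[lk]][2], 30)))
  }

  # epoch that does not cover the window is refused
  short <- eeg_epochs(dat[, , 1:10], fs = fs, lock = "response",
                      times = tms[1:10], trials = trials,
                      recording = e$recording)
  expect_error(suppressMessages(segment_epochs(short)), class = "eegdyn_invalid")

  # no responded trials at all is refused
  none <- e
  none$trials$responded <- FALSE
  expect_error(segment_epochs(none), class = "eegdyn_invalid")
})

test_that("the 50-trial inclusion rule is inclusive and per-lock", {
  counts <- tibble::tibble(
    recording_id = c("A", "A", "B", "B"),
    lock = c("stimulus", "response", "stimulus", "response"),
    n_trials = c(49, 60, 50, 12))
  inc <- apply_inclusion_rule(counts)
  expect_equal(inc$included, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(apply_inclusion_rule(counts, min_trials = 10)$included,
               rep(TRUE, 4))
})
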