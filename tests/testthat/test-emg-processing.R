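test_that("preprocessing suppresses mains and drift and rectifies", {
  fs <- 1200
  t <- seq(0, 5, by = 1 / fs)[-1]
  mains <- emg_recording(t, sin(2 * pi * 50 * t), sin(2 * pi * 50 * t))
  out <- preprocess_emg(mains, rectify = FALSE)
  mid <- t > 1 & t < 4  # away from filter edge transients
  atten_db <- 20 * log10(rms(out$channels$TA[mid]) / rms(sin(2 * pi * 50 * t)[mid]))
  expect_lt(atten_db, -20)
  drift <- emg_recording(t, sin(2 * pi * 2 * t), sin(2 * pi * 2 * t))
  outd <- preprocess_emg(drift, rectify = FALSE)
  expect_lt(20 * log10(rms(outd$channels$TA[mid]) /
                         rms(sin(2 * pi * 2 * t)[mid])), -20)
  # a passband tone survives nearly unchanged
  tone <- emg_recording(t, sin(2 * pi * 120 * t), sin(2 * pi * 120 * t))
  outt <- preprocess_emg(tone, rectify = FALSE)
  expect_equal(rms(outt$channels$TA[mid]), 1 / sqrt(2), tolerance = 0.02)
  zero <- preprocess_emg(emg_recording(t, 0 * t, 0 * t))
  expect_true(all(zero$channels$TA == 0))
  expect_equal(zero$state, "rectified")
  slow_fs <- seq(0, 2, by = 1 / 800)
  expect_error(preprocess_emg(emg_recording(slow_fs, slow_fs, slow_fs)),
               "sample rate")
  expect_error(preprocess_emg(zero), "already")
})

test_that("rms matches closed forms", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)[-1]
  expect_equal(rms(rep(-3, 10)), 3)
  expect_equal(rms(abs(sin(2 * pi * 5 * t))), 1 / sqrt(2), tolerance = 1e-3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_error(rms(numeric(0)), "empty")
})

test_that("mvc_reference takes the max over trials of the peak-centred window RMS", {
  fs <- 1200
  make_trial <- function(level) {
    x <- rep(0.5, 3 * fs)
    x[1500:2400] <- level  # 0.75 s contraction plateau
    x[1950] <- level * (1 + 1e-9)  # maximal sample at the plateau centre
    rectified_recording(x, fs)
  }
  ref <- mvc_reference(lapply(c(100, 180, 150), make_trial), "TA")
  expect_equal(ref$mvc_rms, 180, tolerance = 1e-6)
  expect_equal(ref$n_repetitions, 3)
  # identical trials give that trial's value
  same <- mvc_reference(lapply(c(150, 150, 150), make_trial), "SOL")
  expect_equal(same$mvc_rms, 150, tolerance = 1e-6)
  # trial shorter than the window warns but still computes
  short <- rectified_recording(rep(80, 300), fs)
  w <- testthat::capture_warnings(r <- mvc_reference(list(short, short, short),
                                                    "TA"))
  expect_true(any(grepl("truncat", w)))
  expect_equal(r$mvc_rms, 80)
})

test_that("baseline statistics give mean + SD thresholds", {
  fs <- 1200
  zero <- rectified_recording(rep(0, 2 * fs), fs)
  b0 <- baseline_stats(zero, "TA", onset = 1)
  expect_equal(b0$threshold, 0)
  # hand-computed: {1,1,1,3} repeated keeps mean 1.5; sample SD of the
  # 4-point pattern
  x <- rep(c(1, 1, 1, 3), length.out = 2 * fs)
  bx <- baseline_stats(rectified_recording(x, fs), "TA", onset = 1,
                       pre_window = 4 / fs)
  expect_equal(bx$mean, 1.5)
  expect_equal(bx$sd, 1.0)
  expect_equal(bx$threshold, 2.5)
  expect_error(baseline_stats(zero, "TA", onset = 0.5), "outside")
})

test_that("rectified Gaussian baselines follow folded-normal moments", {
  # Monte-Carlo check: for zero-mean sigma = 1.58, the rectified mean is
  # sigma * sqrt(2/pi) ~ 1.26 and the rectified SD is sigma * sqrt(1 - 2/pi)
  fs <- 1200
  set.seed(99)
  sigma <- 1.58
  x <- abs(rnorm(60 * fs, 0, sigma))
  rec <- rectified_recording(x, fs)
  b <- baseline_stats(rec, "TA", onset = 60, pre_window = 59.9)
  expect_equal(b$mean, sigma * sqrt(2 / pi), tolerance = 0.02)
  expect_equal(b$sd, sigma * sqrt(1 - 2 / pi), tolerance = 0.02)
  expect_equal(b$threshold, sigma * (sqrt(2 / pi) + sqrt(1 - 2 / pi)),
               tolerance = 0.02)
})

test_that("reflex detection enforces the threshold and 10 ms duration criterion", {
  fs <- 1200
  base <- rep(1, 3 * fs)  # flat rectified baseline, SD 0, threshold 1
  ev <- list(onset = 1, duration = 0.8)
  inject <- function(latency_s, dur_s, level) {
    x <- base
    i0 <- round((1 + latency_s) * fs) + 1
    x[i0:(i0 + round(dur_s * fs) - 1)] <- level
    rectified_recording(x, fs)
  }
  # 30 ms burst at 60 ms latency, well above threshold
  hit <- detect_reflex(inject(0.060, 0.030, 5), "TA", ev)
  expect_true(hit$occurred)
  expect_equal(hit$onset_latency_s, 0.060, tolerance = 2 / fs)
  # 5 ms blip: under the 12-sample run requirement
  expect_false(detect_reflex(inject(0.060, 0.005, 5), "TA", ev)$occurred)
  # exactly at threshold: strict inequality, never occurs
  expect_false(detect_reflex(rectified_recording(base, fs), "TA", ev)$occurred)
  # exactly 10 ms at 1200 Hz = 12 samples: detected
  expect_true(detect_reflex(inject(0.1, 12 / fs, 5), "TA", ev)$occurred)
  # 11 samples: not detected
  expect_false(detect_reflex(inject(0.1, 11 / fs, 5), "TA", ev)$occurred)
})

test_that("any supra-threshold burst >= 10 ms is detected and < 10 ms is not", {
  fs <- 1200
  ev <- list(onset = 1, duration = 0.8)
  set.seed(5)
  for (i in 1:25) {
    dur <- sample(3:40, 1) / fs
    lat <- runif(1, 0, 0.7 - dur)
    x <- rep(1, 3 * fs)
    i0 <- round((1 + lat) * fs) + 1
    x[i0:(i0 + round(dur * fs) - 1)] <- runif(1, 2, 10)
    det <- detect_reflex(rectified_recording(x, fs), "TA", ev)
    expect_identical(det$occurred, round(dur * fs) >= 12)
  }
})

test_that("double bursts need two qualifying runs separated by >= 20 ms", {
  fs <- 1200
  ev <- list(onset = 1, duration = 0.8)
  two_bursts <- function(gap_s) {
    x <- rep(1, 3 * fs)
    i0 <- round(1.05 * fs)
    x[i0:(i0 + 35)] <- 5
    j0 <- i0 + 36 + round(gap_s * fs)
    x[j0:(j0 + 35)] <- 5
    rectified_recording(x, fs)
  }
  expect_true(detect_reflex(two_bursts(0.030), "TA", ev)$double_burst)
  expect_false(detect_reflex(two_bursts(0.010), "TA", ev)$double_burst)
})

test_that("reflex occurrence is the percentage of positive trials", {
  occ <- function(flags) reflex_occurrence(flags)
  expect_equal(occ(c(TRUE, FALSE, FALSE, FALSE)), 25)
  expect_equal(occ(rep(TRUE, 4)), 100)
  expect_equal(occ(rep(FALSE, 4)), 0)
  expect_error(reflex_occurrence(list()), "no trials")
  # conservation: occurrence x n / 100 is an integer
  set.seed(8)
  for (n in c(4, 7, 10)) {
    flags <- runif(n) > 0.5
    expect_equal(reflex_occurrence(flags) * n / 100, sum(flags))
  }
})

test_that("single-pulse RMS normalizes by the MVC reference", {
  fs <- 1200
  ev <- list(onset = 1, duration = 0.8)
  mvc <- mvc_reference_from_value("TA", 50)
  rec <- rectified_recording(rep(50, 3 * fs), fs)
  expect_equal(single_pulse_rms(rec, "TA", ev, mvc), 100)
  zero <- rectified_recording(rep(0, 3 * fs), fs)
  expect_equal(single_pulse_rms(zero, "TA", ev, mvc), 0)
  # invariance to a common gain on signal and reference
  g <- 7.3
  rec_g <- rectified_recording(rep(50 * g, 3 * fs), fs)
  mvc_g <- mvc_reference_from_value("TA", 50 * g)
  expect_equal(single_pulse_rms(rec_g, "TA", ev, mvc_g), 100)
})

test_that("cyclic RMS ratio compares stimulation windows to the rest period", {
  fs <- 1200
  sch <- cyclic_protocol(5, n_cycles = 2, lead_in_rest = 5)
  total <- 16
  t <- (seq_len(total * fs) - 1) / fs
  x <- rep(2, length(t))
  stim <- rep(FALSE, length(t))
  for (i in seq_len(nrow(sch$events))) {
    e <- sch$events[i, ]
    stim[t >= e$onset & t < e$onset + e$duration] <- TRUE
  }
  rec1 <- rectified_recording(x, fs)
  expect_equal(cyclic_rms_ratio(rec1, "TA", sch), 1)
  x3 <- x; x3[stim] <- 6  # 3x the rest level during stimulation
  expect_equal(cyclic_rms_ratio(rectified_recording(x3, fs), "TA", sch), 3)
  expect_error(cyclic_rms_ratio(rec1, "TA",
                                single_pulse_protocol(seed = 1)), "cyclic")
  late <- cyclic_protocol(5, n_cycles = 1, lead_in_rest = 2)
  expect_error(cyclic_rms_ratio(rec1, "TA", late), "rest")
})

test_that("baseline quality flag drops trials with outlying noise", {
  mk <- function(sd) structure(list(sd = sd), class = "baseline_stats")
  bl <- lapply(c(1, 1.2, 0.9, 1.1, 20), mk)
  expect_equal(baseline_quality_flag(bl), c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("EMG CSV round-trips preserve channels and trigger", {
  prof <- subject_profile()
  sch <- single_pulse_protocol(pressures = 2, rise_speeds = "slow",
                               locations = "heel", reps = 1,
                               lead_in_rest = 1, seed = 1)
  ses <- gen_session(prof, sch, seed = 2)
  p <- tempfile(fileext = ".csv")
  write_emg_csv(ses$emg, p)
  back <- read_emg_csv(p)
  expect_equal(back$channels$TA, ses$emg$channels$TA, tolerance = 1e-12)
  expect_equal(back$trigger, ses$emg$trigger)
  expect_equal(back$state, "raw")
})
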