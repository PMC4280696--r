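test_that("baseline EMG noise is calibrated in rectified RMS and reproducible", {
  x <- gen_baseline_emg(1.26, 30, 1200, seed = 2)
  expect_equal(sqrt(mean(abs(x)^2)), 1.26, tolerance = 0.02)
  x2 <- gen_baseline_emg(1.26, 30, 1200, seed = 2)
  expect_identical(x, x2)
  xd <- gen_baseline_emg(2.52, 30, 1200, seed = 2)
  expect_equal(sqrt(mean(xd^2)) / sqrt(mean(x^2)), 2, tolerance = 0.02)
  # in the analysis band: negligible DC and mains-free after preprocessing
  expect_lt(abs(mean(x)), 0.05)
})

test_that("reflex bursts hit the commanded peak and are detectable", {
  b <- gen_reflex_burst(54.5, 68.89, seed = 3)
  expect_equal(max(abs(b)), 0.545 * 68.89, tolerance = 1e-9)
  expect_equal(length(b), 960)
  expect_identical(gen_reflex_burst(0, 68.89, seed = 3), rep(0, 960))
  # a 54.5 %MVC burst against a rest-level baseline trips the detector
  fs <- 1200
  base <- gen_baseline_emg(1.32, 3, fs, seed = 4)
  i0 <- round(1 * fs) + 1
  base[i0:(i0 + 959)] <- base[i0:(i0 + 959)] + b
  rec <- preprocess_emg(emg_recording((seq_along(base) - 1) / fs, base, base))
  det <- detect_reflex(rec, "SOL", list(onset = 1, duration = 0.8))
  expect_true(det$occurred)
  expect_lt(abs(det$onset_latency_s - 0.06), 0.02)
  # double bursts built by the generator are reported as double
  bd <- gen_reflex_burst(150, 189.16, double = TRUE, seed = 5)
  base2 <- gen_baseline_emg(1.26, 3, fs, seed = 6)
  base2[i0:(i0 + 959)] <- base2[i0:(i0 + 959)] + bd
  rec2 <- preprocess_emg(emg_recording((seq_along(base2) - 1) / fs,
                                       base2, base2))
  det2 <- detect_reflex(rec2, "TA", list(onset = 1, duration = 0.8))
  expect_true(det2$double_burst)
})

test_that("synthetic MVC trials recover the generating reference within 5%", {
  prof <- subject_profile()
  trials <- lapply(gen_mvc_trials(prof, seed = 5), preprocess_emg)
  for (m in c("TA", "SOL")) {
    ref <- mvc_reference(trials, m)
    expect_equal(ref$mvc_rms, prof$mvc_rms[[m]], tolerance = 0.05)
  }
})

test_that("marker traces hold the neutral angle and encode plate excursions", {
  prof <- subject_profile()
  empty <- cyclic_protocol(5, n_cycles = 1, lead_in_rest = 1)
  empty$events <- empty$events[0, ]
  mk <- gen_marker_traces(prof, empty, seed = 7, total_duration = 5)
  th <- ankle_angle(mk)$theta_deg
  expect_equal(mean(th), 150, tolerance = 0.05)
  expect_lt(stats::sd(th), 0.2)  # only jitter
  # heel and forefoot events recover the generating deltas with the
  # documented signs
  sch <- single_pulse_protocol(pressures = 3.5, rise_speeds = "slow",
                               locations = c("heel", "forefoot"), reps = 4,
                               interval = 4, lead_in_rest = 2, seed = 8)
  mk2 <- gen_marker_traces(prof, sch, seed = 9)
  ac <- analyze_angle_changes(mk2, sch)
  heel <- ac$change_deg[ac$location == "heel"]
  fore <- ac$change_deg[ac$location == "forefoot"]
  expect_true(all(heel < 0) && all(fore > 0))
  expect_equal(mean(heel), -1.33, tolerance = 0.05)
  expect_equal(mean(fore), 1.07, tolerance = 0.05)
})

test_that("sessions are reproducible and ground truth matches the draws", {
  prof <- subject_profile(reflex_probability = 0.5)
  sch <- single_pulse_protocol(pressures = c(2, 3.5),
                               rise_speeds = c("slow", "fast"),
                               locations = "heel", reps = 2, interval = 3,
                               lead_in_rest = 2, seed = 3)
  s1 <- gen_session(prof, sch, seed = 10)
  s2 <- gen_session(prof, sch, seed = 10)
  expect_identical(s1$emg$channels, s2$emg$channels)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_equal(nrow(s1$ground_truth), nrow(sch$events))
  expect_true(all(s1$ground_truth$latency_is_placeholder))
  # trigger is high exactly during events
  expect_equal(sum(s1$emg$trigger), 8 * 960)
})

test_that("extreme probabilities propagate through the whole pipeline", {
  mvc <- default_mvc_refs()
  sch <- single_pulse_protocol(pressures = 3.5, rise_speeds = "slow",
                               locations = "heel", reps = 4, interval = 3,
                               lead_in_rest = 2, seed = 4)
  certain <- subject_profile(reflex_probability = 1, pressure_prob_gain = 0,
                             reflex_gain = c(heel_TA = 10, heel_SOL = 10,
                                             forefoot_TA = 10,
                                             forefoot_SOL = 10))
  ses1 <- gen_session(certain, sch, seed = 11)
  tr1 <- analyze_single_pulse(ses1$emg, ses1$schedule, mvc)
  expect_equal(reflex_occurrence(tr1$occurred[tr1$muscle == "TA"]), 100)
  never <- subject_profile(reflex_probability = 0)
  ses0 <- gen_session(never, sch, seed = 12)
  tr0 <- analyze_single_pulse(ses0$emg, ses0$schedule, mvc)
  expect_equal(reflex_occurrence(tr0$occurred[tr0$muscle == "TA"]), 0)
  # a quiet cyclic session keeps the stimulation/rest RMS ratio near 1
  cyc <- cyclic_protocol(5, n_cycles = 9, lead_in_rest = 5)
  sesq <- gen_session(never, cyc, seed = 13)
  ratio <- cyclic_rms_ratio(preprocess_emg(sesq$emg), "SOL", cyc)
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("higher pressure yields non-decreasing EMG responses in the model", {
  mvc <- default_mvc_refs()
  # gains large enough that the burst dominates the 0.8 s window RMS
  prof <- subject_profile(reflex_probability = 1, pressure_prob_gain = 0,
                          reflex_gain = c(heel_TA = 10, heel_SOL = 10,
                                          forefoot_TA = 10,
                                          forefoot_SOL = 10))
  sch <- single_pulse_protocol(pressures = c(2, 2.5, 3, 3.5),
                               rise_speeds = "slow", locations = "heel",
                               reps = 6, interval = 3, lead_in_rest = 2,
                               seed = 5)
  ses <- gen_session(prof, sch, seed = 14)
  tr <- analyze_single_pulse(ses$emg, ses$schedule, mvc)
  sol <- tr[tr$muscle == "SOL", ]
  by_p <- tapply(sol$rms_pct_mvc, sol$pressure, mean)
  expect_true(all(diff(by_p[order(as.numeric(names(by_p)))]) >= 0))
})

test_that("amplitude recovery: detected peaks track the generating %MVC", {
  mvc <- default_mvc_refs()
  sch <- single_pulse_protocol(pressures = 2, rise_speeds = "slow",
                               locations = "heel", reps = 6, interval = 3,
                               lead_in_rest = 2, seed = 6)
  for (amp_per_bar in c(5, 25, 50)) {
    prof <- subject_profile(reflex_probability = 1, pressure_prob_gain = 0,
                            reflex_gain = c(heel_TA = amp_per_bar,
                                            heel_SOL = amp_per_bar,
                                            forefoot_TA = amp_per_bar,
                                            forefoot_SOL = amp_per_bar))
    ses <- gen_session(prof, sch, seed = 20 + amp_per_bar)
    tr <- analyze_single_pulse(ses$emg, ses$schedule, mvc)
    ta <- tr[tr$muscle == "TA", ]
    target <- amp_per_bar * 2  # gain x 2 bar
    expect_equal(mean(ta$peak_pct_mvc), target, tolerance = 0.10)
  }
})
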