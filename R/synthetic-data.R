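# Synthetic session generator: EMG, marker and trigger series with known
# ground truth, emulating the statistical structure the analysis assumes --
# rest-level rectified EMG, MVC bursts, stimulus-locked reflex bursts that
# grow with pressure and rise speed, plate-induced ankle-angle ramps and
# optional reflex-induced perturbations.

#' Synthetic subject profile
#'
#' Generating parameters of one simulated subject. Defaults follow the
#' group means of the bundled reference tables: rest rectified RMS 1.26 uV
#' (TA) / 1.32 uV (SOL), MVC 189.16 / 68.89 uV, a neutral supine ankle angle
#' of 150 degrees, and plate-induced angle changes of -1.33 degrees (heel)
#' and +1.07 degrees (forefoot).
#'
#' @param subject subject identifier.
#' @param rest_rms named vector, rectified-RMS rest level per muscle, uV.
#' @param mvc_rms named vector, MVC reference per muscle, uV.
#' @param reflex_gain named vector `heel_TA`, `heel_SOL`, `forefoot_TA`,
#'   `forefoot_SOL`: reflex burst amplitude in %MVC_RMS per bar of pressure
#'   (slow stimuli; fast stimuli are multiplied by `fast_multiplier`).
#' @param reflex_probability probability that a slow stimulus at the lowest
#'   pressure evokes a reflex; see `pressure_prob_gain` / `fast_multiplier`.
#' @param pressure_prob_gain additive increase of the reflex probability per
#'   bar above 2 bar.
#' @param fast_multiplier factor (> 1) applied to both reflex probability
#'   and amplitude for fast (0.05 s rise) stimuli.
#' @param latency_s reflex onset latency after stimulus onset, seconds. No
#'   measured latencies back this default; 0.06 s is a placeholder and is
#'   labelled as such in ground-truth output.
#' @param burst_duration_s reflex burst duration, seconds.
#' @param perturbation_susceptible if TRUE, strong fast stimuli add a
#'   transient extra ~1 degree ankle deflection and a double EMG burst.
#' @param neutral_angle_deg resting ankle angle, degrees.
#' @param angle_change_deg named vector `heel`, `forefoot`: plate-induced
#'   angle change, degrees (signed).
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject = "SYN1",
                            rest_rms = c(TA = 1.26, SOL = 1.32),
                            mvc_rms = c(TA = 189.16, SOL = 68.89),
                            reflex_gain = c(heel_TA = 0.8, heel_SOL = 1.0,
                                            forefoot_TA = 0.6,
                                            forefoot_SOL = 0.8),
                            reflex_probability = 0.25,
                            pressure_prob_gain = 0.1,
                            fast_multiplier = 2.5,
                            latency_s = 0.06,
                            burst_duration_s = 0.15,
                            perturbation_susceptible = FALSE,
                            neutral_angle_deg = 150,
                            angle_change_deg = c(heel = -1.33,
                                                 forefoot = 1.07)) {
  stopifnot(all(rest_rms > 0), all(mvc_rms > 0), all(reflex_gain >= 0),
            reflex_probability >= 0, reflex_probability <= 1,
            fast_multiplier > 1, latency_s >= 0)
  structure(list(subject = subject, rest_rms = rest_rms, mvc_rms = mvc_rms,
                 reflex_gain = reflex_gain,
                 reflex_probability = reflex_probability,
                 pressure_prob_gain = pressure_prob_gain,
                 fast_multiplier = fast_multiplier,
                 latency_s = latency_s,
                 burst_duration_s = burst_duration_s,
                 perturbation_susceptible = perturbation_susceptible,
                 neutral_angle_deg = neutral_angle_deg,
                 angle_change_deg = angle_change_deg),
            class = "subject_profile")
}

# Band-limited (5-500 Hz) standard-normal-scale noise of length n.
band_noise <- function(n, sample_rate, band = c(5, 500)) {
  pad <- 200
  x <- stats::rnorm(n + 2 * pad)
  bp <- signal::butter(2, band / (sample_rate / 2), type = "pass")
  y <- signal::filtfilt(bp, x)[(pad + 1):(pad + n)]
  y / stats::sd(y)
}

#' Baseline (resting) EMG noise
#'
#' Band-limited Gaussian noise scaled so that its rectified RMS equals
#' `rest_rms` (rectification leaves the RMS of a zero-mean signal
#' unchanged). Seeded and reproducible.
#'
#' @param rest_rms target rectified RMS, uV.
#' @param duration series length, seconds.
#' @param sample_rate samples per second.
#' @param seed integer seed; NULL uses the current RNG state.
#' @return numeric series, uV.
#' @export
gen_baseline_emg <- function(rest_rms, duration, sample_rate = 1200,
                             seed = NULL) {
  stopifnot(rest_rms > 0)
  n <- round(duration * sample_rate)
  with_seed(seed, {
    y <- band_noise(n, sample_rate)
    y <- y - mean(y)
    rest_rms * y / sqrt(mean(y^2))
  })
}

# Tukey (tapered-cosine) envelope of length n with taper fraction per edge.
tukey_window <- function(n, taper = 0.15) {
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < taper
  hi <- t > 1 - taper
  w[lo] <- 0.5 * (1 - cos(pi * t[lo] / taper))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - t[hi]) / taper))
  w
}

# Noise carrier whose magnitude never falls below `floor` of its envelope,
# so the rectified burst tracks the envelope and the duration criterion
# reflects the commanded burst duration rather than carrier zero crossings.
floored_carrier <- function(n, sample_rate, floor = 0.55) {
  v <- band_noise(n, sample_rate, band = c(30, 300))
  v <- v / max(abs(v))
  sign(v) * (floor + (1 - floor) * abs(v))
}

#' Stimulus-locked reflex EMG burst
#'
#' Additive burst for one stimulation window: amplitude-modulated
#' band-limited noise under a tapered-cosine envelope, with the carrier
#' magnitude floored so the rectified burst stays close to the envelope.
#' The peak rectified value equals `amplitude_pct_mvc`/100 x `mvc_rms`.
#' With `double = TRUE` two bursts separated by a below-threshold gap of at
#' least 20 ms are produced (the double-burst signature of a strong
#' withdrawal-like reflex).
#'
#' @param amplitude_pct_mvc peak amplitude, %MVC_RMS.
#' @param mvc_rms MVC reference, uV.
#' @param latency burst onset after the window start, seconds.
#' @param burst_duration single-burst duration, seconds.
#' @param double generate a double burst.
#' @param window window length covered by the returned series, seconds.
#' @param sample_rate samples per second.
#' @param seed integer seed.
#' @return numeric series of length `round(window * sample_rate)`, uV, to be
#'   added to the raw EMG starting at the stimulus onset.
#' @export
gen_reflex_burst <- function(amplitude_pct_mvc, mvc_rms, latency = 0.06,
                             burst_duration = 0.15, double = FALSE,
                             window = 0.8, sample_rate = 1200,
                             seed = NULL) {
  stopifnot(amplitude_pct_mvc >= 0)
  n <- round(window * sample_rate)
  out <- numeric(n)
  if (amplitude_pct_mvc == 0) return(out)
  target <- amplitude_pct_mvc / 100 * mvc_rms
  with_seed(seed, {
    nb <- round(burst_duration * sample_rate)
    starts <- round(latency * sample_rate) + 1
    if (double) {
      # well above the 20 ms separation criterion: the narrow notch filter
      # rings for tens of ms past a burst, and the separation must survive
      gap <- round(0.10 * sample_rate)
      starts <- c(starts, starts + nb + gap)
    }
    for (s in starts) {
      e <- min(s + nb - 1, n)
      if (s > n) next
      len <- e - s + 1
      burst <- tukey_window(len) * floored_carrier(len, sample_rate)
      out[s:e] <- out[s:e] + burst
    }
    # shape the burst to the analysis band before scaling the peak, so the
    # peak survives the processing chain instead of ringing above it
    pad <- 200
    bp <- signal::butter(2, c(5, 500) / (sample_rate / 2), type = "pass")
    shaped <- signal::filtfilt(bp, c(numeric(pad), out, numeric(pad)))
    shaped <- signal::filtfilt(notch_filter(50, sample_rate, 30), shaped)
    out <- shaped[(pad + 1):(pad + n)]
    out * target / max(abs(out))
  })
}

#' Synthetic MVC trials
#'
#' Maximal-voluntary-contraction recordings: rest-level noise with a central
#' 1 s contraction burst calibrated so that the rectified RMS in the 500 ms
#' window at the peak equals the profile's `mvc_rms`.
#'
#' @param profile a [subject_profile()].
#' @param n_trials number of repetitions (three in the protocol modelled).
#' @param duration trial length, seconds.
#' @param sample_rate samples per second.
#' @param seed integer seed.
#' @return list of raw `emg_recording`s.
#' @export
gen_mvc_trials <- function(profile, n_trials = 3, duration = 3,
                           sample_rate = 1200, seed = 1) {
  with_seed(seed, lapply(seq_len(n_trials), function(i) {
    n <- round(duration * sample_rate)
    times <- (seq_len(n) - 1) / sample_rate
    chans <- lapply(c(TA = "TA", SOL = "SOL"), function(m) {
      base <- gen_baseline_emg(profile$rest_rms[[m]], duration, sample_rate)
      nb <- round(1 * sample_rate)
      s <- round((duration / 2 - 0.5) * sample_rate)
      burst <- tukey_window(nb) * floored_carrier(nb, sample_rate)
      # calibrate the central 500 ms rectified RMS to the MVC target
      ctr <- (s + round(0.25 * sample_rate)):(s + round(0.75 * sample_rate))
      scale <- profile$mvc_rms[[m]] /
        sqrt(mean(burst[ctr - s + 1]^2))
      base[s:(s + nb - 1)] <- base[s:(s + nb - 1)] + scale * burst
      base
    })
    emg_recording(times, chans$TA, chans$SOL)
  }))
}

# Effective reflex probability and burst amplitude (%MVC) for one event.
event_response <- function(profile, location, pressure, rise_speed, muscle) {
  fm <- if (identical(rise_speed, "fast")) profile$fast_multiplier else 1
  p <- profile$reflex_probability *
    (1 + profile$pressure_prob_gain * (pressure - 2)) * fm
  amp <- profile$reflex_gain[[paste(location, muscle, sep = "_")]] *
    pressure * fm
  list(prob = min(1, p), amplitude_pct = amp)
}

#' Synthetic marker trajectories
#'
#' Knee and ankle markers are fixed (0.1 mm jitter); the metatarsal rotates
#' about the ankle so the shank-foot angle follows the neutral angle with a
#' ramp-and-hold excursion per scheduled event (heel negative, forefoot
#' positive, ramp equal to the plate rise time). Events flagged in
#' `perturb_events` additionally receive a transient extra deflection of
#' `perturbation_deg` (default 1 degree) mid-stimulus.
#'
#' @param profile a [subject_profile()].
#' @param schedule a `protocol_schedule`.
#' @param seed integer seed.
#' @param sample_rate marker frame rate, Hz.
#' @param total_duration series length, seconds; default covers the schedule.
#' @param perturb_events logical per event; NULL applies the profile rule
#'   (susceptible subject, fast stimulus at >= 3.5 bar).
#' @param perturbation_deg magnitude of the extra transient deflection.
#' @param jitter_sd marker jitter SD, metres.
#' @return a `marker_frames` object.
#' @export
gen_marker_traces <- function(profile, schedule, seed = NULL,
                              sample_rate = 100, total_duration = NULL,
                              perturb_events = NULL,
                              perturbation_deg = 1, jitter_sd = 1e-4) {
  ev <- schedule$events
  if (is.null(total_duration)) {
    total_duration <- (if (nrow(ev)) max(ev$onset + ev$duration) else 0) +
      max(1, schedule$lead_in_rest)
  }
  if (is.null(perturb_events)) {
    perturb_events <- profile$perturbation_susceptible &
      ev$rise_speed == "fast" & ev$pressure >= 3.5
  }
  n <- round(total_duration * sample_rate)
  times <- (seq_len(n) - 1) / sample_rate
  theta <- rep(profile$neutral_angle_deg, n)
  for (i in seq_len(nrow(ev))) {
    rise <- if (identical(ev$rise_speed[i], "fast")) 0.05 else 0.2
    delta <- profile$angle_change_deg[[ev$location[i]]]
    rel <- times - ev$onset[i]
    dur <- ev$duration[i]
    ramp <- pmin(1, pmax(0, rel / rise)) -
      pmin(1, pmax(0, (rel - dur) / rise))  # rise, hold, symmetric fall
    theta <- theta + delta * ramp
    if (isTRUE(perturb_events[i])) {
      b0 <- ev$onset[i] + 0.25; b1 <- min(ev$onset[i] + 0.45, ev$onset[i] + dur)
      inb <- times >= b0 & times <= b1
      bump <- 0.5 * (1 - cos(2 * pi * (times[inb] - b0) / (b1 - b0)))
      theta[inb] <- theta[inb] + sign(delta) * perturbation_deg * bump
    }
  }
  with_seed(seed, {
    ankle <- cbind(0, 0.1)[rep(1, n), ]
    knee <- cbind(0, 0.5)[rep(1, n), ]
    az <- (90 - theta) * pi / 180   # foot direction relative to +x axis
    meta <- cbind(ankle[, 1] + 0.15 * cos(az), ankle[, 2] + 0.15 * sin(az))
    jit <- function(m) m + matrix(stats::rnorm(2 * n, 0, jitter_sd), n, 2)
    marker_frames(times, jit(knee), jit(ankle), jit(meta))
  })
}

#' Generate a complete synthetic session
#'
#' Composes baseline EMG, Bernoulli-drawn reflex bursts, marker trajectories
#' and trigger traces for a stimulation schedule. For each event the reflex
#' probability is the profile's base probability, increased with pressure
#' and multiplied by `fast_multiplier` for fast stimuli (capped at 1); burst
#' amplitudes are linear in pressure through `reflex_gain`. Every draw is
#' recorded in the ground-truth table. A perturbation (extra ankle
#' deflection plus a double burst) is injected when the subject is
#' susceptible, the stimulus is fast at >= 3.5 bar, and the reflex fired.
#'
#' @param profile a [subject_profile()].
#' @param schedule a `protocol_schedule`.
#' @param seed integer seed driving all randomness in the session.
#' @param emg_rate EMG sample rate, Hz.
#' @param marker_rate marker frame rate, Hz.
#' @return an object of class `synthetic_session`: `emg` (raw
#'   `emg_recording` with trigger), `markers`, `schedule`, `ground_truth`
#'   (one row per event; `latency_s` is the placeholder generator value, not
#'   a measured quantity).
#' @export
gen_session <- function(profile, schedule, seed = 1, emg_rate = 1200,
                        marker_rate = 100) {
  ev <- schedule$events
  total <- (if (nrow(ev)) max(ev$onset + ev$duration) else 0) +
    max(1, schedule$lead_in_rest)
  with_seed(seed, {
    n <- round(total * emg_rate)
    times <- (seq_len(n) - 1) / emg_rate
    chans <- list(TA = gen_baseline_emg(profile$rest_rms[["TA"]], total, emg_rate),
                  SOL = gen_baseline_emg(profile$rest_rms[["SOL"]], total, emg_rate))
    occurred <- logical(nrow(ev))
    perturbed <- logical(nrow(ev))
    amp_ta <- amp_sol <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      resp_ta <- event_response(profile, ev$location[i], ev$pressure[i],
                                ev$rise_speed[i], "TA")
      resp_sol <- event_response(profile, ev$location[i], ev$pressure[i],
                                 ev$rise_speed[i], "SOL")
      occurred[i] <- stats::runif(1) < resp_ta$prob
      if (!occurred[i]) next
      perturbed[i] <- profile$perturbation_susceptible &&
        identical(ev$rise_speed[i], "fast") && ev$pressure[i] >= 3.5
      amp_ta[i] <- resp_ta$amplitude_pct
      amp_sol[i] <- resp_sol$amplitude_pct
      win <- min(ev$duration[i], 0.8)
      idx <- window_idx(times, ev$onset[i], ev$onset[i] + win)
      for (m in c("TA", "SOL")) {
        amp <- if (m == "TA") amp_ta[i] else amp_sol[i]
        if (amp <= 0) next
        chans[[m]][idx] <- chans[[m]][idx] +
          gen_reflex_burst(amp, profile$mvc_rms[[m]],
                           latency = profile$latency_s,
                           burst_duration = profile$burst_duration_s,
                           double = perturbed[i], window = win,
                           sample_rate = emg_rate)
      }
    }
    trig <- trigger_trace(schedule, emg_rate, total)
    emg <- emg_recording(times, chans$TA, chans$SOL,
                         trigger = pmax(trig$heel, trig$forefoot))
    markers <- gen_marker_traces(profile, schedule,
                                 sample_rate = marker_rate,
                                 total_duration = total,
                                 perturb_events = perturbed)
    truth <- cbind(ev,
                   data.frame(reflex = occurred,
                              amplitude_pct_ta = amp_ta,
                              amplitude_pct_sol = amp_sol,
                              latency_s = ifelse(occurred, profile$latency_s, NA),
                              latency_is_placeholder = TRUE,
                              angle_change_deg = vapply(ev$location, function(l)
                                profile$angle_change_deg[[l]], numeric(1)),
                              perturbation = perturbed))
    structure(list(emg = emg, markers = markers, schedule = schedule,
                   ground_truth = truth, profile = profile),
              class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("<synthetic_session>", nrow(x$ground_truth), "events,",
      length(x$emg$times), "EMG samples,",
      length(x$markers$times), "marker frames\n")
  cat("  reflexes drawn:", sum(x$ground_truth$reflex), "/",
      nrow(x$ground_truth), "\n")
  invisible(x)
}

#' MVC reference from a known value
#'
#' Wraps an already-known MVC RMS (for example a synthetic profile's
#' generating value) in the object [single_pulse_rms()] and
#' [detect_reflex()] expect.
#'
#' @param muscle `"TA"` or `"SOL"`.
#' @param mvc_rms reference value, uV.
#' @return an `mvc_reference`.
#' @export
mvc_reference_from_value <- function(muscle, mvc_rms) {
  structure(list(muscle = muscle, mvc_rms = mvc_rms, window = 0.5,
                 n_repetitions = 0L, per_trial = numeric(0)),
            class = "mvc_reference")
}
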