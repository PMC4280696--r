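# Surface-EMG chain: band-pass + notch filtering and rectification, MVC
# reference extraction, baseline statistics, threshold/duration reflex
# detection, occurrence scoring, and normalized RMS summaries.

#' Two-channel EMG recording
#'
#' Tibialis anterior (TA) and soleus (SOL) series in microvolts on a shared
#' uniform time grid, with the stimulation trigger channel. `state` tracks
#' preprocessing: `raw` -> `filtered` -> `rectified`.
#'
#' @param times sample times, seconds (uniform grid, 1200 Hz in the
#'   recordings this models).
#' @param ta,sol channel series, microvolts.
#' @param trigger binary stimulation trigger series (optional).
#' @param state preprocessing state.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(times, ta, sol, trigger = NULL, state = "raw") {
  n <- length(times)
  stopifnot(length(ta) == n, length(sol) == n,
            is.null(trigger) || length(trigger) == n,
            state %in% c("raw", "filtered", "rectified"))
  if (n > 1) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("non-uniform sampling")
  }
  structure(list(times = times,
                 channels = list(TA = ta, SOL = sol),
                 trigger = trigger, state = state,
                 sample_rate = if (n > 1) 1 / (times[2] - times[1]) else NA),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording>", length(x$times), "samples at",
      round(x$sample_rate), "Hz, state:", x$state, "\n")
  invisible(x)
}

# Biquad notch (constrained pole-zero design): zeros on the unit circle at
# +-f0, poles inside at bandwidth f0/Q. Unit gain away from the notch.
notch_filter <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b / a[1], a / a[1])
}

#' Filter and rectify an EMG recording
#'
#' Zero-phase band-pass (5--500 Hz, 4th-order Butterworth) and 50 Hz notch
#' (quality factor 30), then full-wave rectification (absolute value).
#' Zero-phase application preserves burst onset latencies; the high-pass edge
#' removes the DC component before rectification.
#'
#' @param recording an [emg_recording()] in `raw` state.
#' @param band band-pass edges, Hz.
#' @param notch_hz mains frequency to notch out; NULL disables.
#' @param notch_q notch quality factor.
#' @param order Butterworth order of the band-pass.
#' @param rectify apply full-wave rectification after filtering.
#' @return the recording with filtered (and rectified) channels.
#' @export
preprocess_emg <- function(recording, band = c(5, 500), notch_hz = 50,
                           notch_q = 30, order = 4, rectify = TRUE) {
  if (recording$state != "raw") stop("recording already preprocessed")
  fs <- recording$sample_rate
  if (fs <= 2 * band[2]) {
    stop("sample rate ", fs, " Hz too low for a ", band[2], " Hz band edge")
  }
  bp <- signal::butter(order / 2, band / (fs / 2), type = "pass")
  nf <- if (!is.null(notch_hz)) notch_filter(notch_hz, fs, notch_q)
  recording$channels <- lapply(recording$channels, function(x) {
    y <- signal::filtfilt(bp, x)
    if (!is.null(nf)) y <- signal::filtfilt(nf, y)
    if (rectify) abs(y) else y
  })
  recording$state <- if (rectify) "rectified" else "filtered"
  recording
}

#' Root-mean-square amplitude over a window
#'
#' @param x numeric series (or an `emg_recording` channel via `muscle`).
#' @param times sample times matching `x`; required with `start`/`end`.
#' @param start,end window bounds in seconds (half-open); omitted = whole
#'   series.
#' @return RMS amplitude (same units as `x`).
#' @export
rms <- function(x, times = NULL, start = NULL, end = NULL) {
  if (!is.null(start) || !is.null(end)) {
    if (is.null(times)) stop("times required for a windowed RMS")
    x <- x[window_idx(times, start, end)]
  }
  if (!length(x)) stop("empty RMS window")
  sqrt(mean(x^2))
}

#' MVC normalization reference
#'
#' For each maximal-voluntary-contraction trial, the RMS over a 500 ms window
#' centered at the maximal rectified sample is computed (the window is
#' truncated at the trial edges); the reference is the maximum over the
#' trials. EMG amplitudes are later expressed as a percentage of this value
#' (%MVC_RMS).
#'
#' @param recordings list of preprocessed (rectified) `emg_recording` MVC
#'   trials (conventionally three).
#' @param muscle `"TA"` or `"SOL"`.
#' @param window RMS window length, seconds.
#' @return an object of class `mvc_reference` with `muscle`, `mvc_rms` (uV),
#'   `window`, `n_repetitions` and the per-trial values.
#' @export
mvc_reference <- function(recordings, muscle = c("TA", "SOL"),
                          window = 0.5) {
  muscle <- match.arg(muscle)
  per_trial <- vapply(recordings, function(rec) {
    if (rec$state != "rectified") stop("MVC trials must be rectified")
    x <- rec$channels[[muscle]]
    fs <- rec$sample_rate
    if (length(x) < window * fs) {
      warning("MVC trial shorter than the ", window * 1000,
              " ms window; truncating")
    }
    peak <- which.max(x)
    half <- round(window * fs / 2)
    lo <- max(1, peak - half)
    hi <- min(length(x), peak + half - 1)
    sqrt(mean(x[lo:hi]^2))
  }, numeric(1))
  structure(list(muscle = muscle, mvc_rms = max(per_trial), window = window,
                 n_repetitions = length(recordings), per_trial = per_trial),
            class = "mvc_reference")
}

#' Baseline statistics and reflex threshold before a stimulus
#'
#' Mean and sample SD of the rectified EMG over the pre-stimulus window
#' (0.8 s by default); the reflex threshold is mean + SD. Statistics are
#' computed on the rectified, filtered signal so that threshold and burst are
#' on the same scale; `domain = "raw"` preserves the literal signed-signal
#' reading, whose mean is approximately zero.
#'
#' @param recording preprocessed `emg_recording`.
#' @param muscle `"TA"` or `"SOL"`.
#' @param onset stimulus onset, seconds.
#' @param pre_window baseline length before onset, seconds.
#' @param domain `"rectified"` (default) or `"raw"`; with `"raw"` the
#'   recording must still be in `filtered` state.
#' @return an object of class `baseline_stats` with `mean`, `sd`,
#'   `threshold` (uV) and the window description.
#' @export
baseline_stats <- function(recording, muscle = c("TA", "SOL"), onset,
                           pre_window = 0.8,
                           domain = c("rectified", "raw")) {
  muscle <- match.arg(muscle)
  domain <- match.arg(domain)
  x <- recording$channels[[muscle]]
  idx <- window_idx(recording$times, onset - pre_window, onset)
  seg <- x[idx]
  m <- mean(seg)
  s <- stats::sd(seg)
  structure(list(muscle = muscle, window = pre_window, domain = domain,
                 mean = m, sd = s, threshold = m + s),
            class = "baseline_stats")
}

# Runs of consecutive TRUEs with length >= need; returns start/length pairs.
qualifying_runs <- function(above, need) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= need
  data.frame(start = starts[keep], length = r$lengths[keep],
             end = ends[keep])
}

#' Detect a mechanically evoked reflex in one trial
#'
#' A reflex occurred when the rectified EMG stays strictly above the baseline
#' mean + SD threshold for at least `min_duration` (10 ms = 12 samples at
#' 1200 Hz) within the stimulation window. Two qualifying bursts separated by
#' at least `double_gap` below threshold are flagged as a double burst, the
#' signature of a strong withdrawal-like reflex.
#'
#' @param recording preprocessed (rectified) `emg_recording`.
#' @param muscle `"TA"` or `"SOL"`.
#' @param event schedule event row (`onset`, `duration`).
#' @param baseline a [baseline_stats()] for this trial; computed from the
#'   0.8 s pre-stimulus window when NULL.
#' @param mvc optional [mvc_reference()] used to express the peak in
#'   %MVC_RMS.
#' @param min_duration duration criterion, seconds.
#' @param double_gap minimum below-threshold gap between the two bursts of a
#'   double burst, seconds.
#' @param window analysis window after onset, seconds (the 0.8 s stimulus).
#' @return an object of class `reflex_event`: `occurred`, `onset_latency_s`,
#'   `peak_amplitude` (%MVC_RMS when `mvc` given, else uV), `double_burst`,
#'   `threshold_uv`.
#' @export
detect_reflex <- function(recording, muscle = c("TA", "SOL"), event,
                          baseline = NULL, mvc = NULL,
                          min_duration = 0.010, double_gap = 0.020,
                          window = 0.8) {
  muscle <- match.arg(muscle)
  if (recording$state != "rectified") {
    stop("detect_reflex requires a rectified recording")
  }
  if (is.null(baseline)) {
    baseline <- baseline_stats(recording, muscle, event$onset)
  }
  fs <- recording$sample_rate
  idx <- window_idx(recording$times, event$onset, event$onset + window)
  seg <- recording$channels[[muscle]][idx]
  need <- max(1L, round(min_duration * fs))
  runs <- qualifying_runs(seg > baseline$threshold, need)
  occurred <- nrow(runs) > 0
  # Qualifying runs separated by less than double_gap belong to one burst
  # (brief dips at carrier zero crossings do not split a burst); a double
  # burst needs two bursts whose separation is at least double_gap.
  double <- FALSE
  if (nrow(runs) >= 2) {
    gaps <- runs$start[-1] - runs$end[-nrow(runs)] - 1
    double <- any(gaps >= round(double_gap * fs))
  }
  peak <- max(seg)
  if (!is.null(mvc)) peak <- 100 * peak / mvc$mvc_rms
  structure(list(muscle = muscle, occurred = occurred,
                 onset_latency_s = if (occurred) (runs$start[1] - 1) / fs else NA_real_,
                 peak_amplitude = peak, double_burst = double,
                 threshold_uv = baseline$threshold),
            class = "reflex_event")
}

#' Reflex occurrence percentage
#'
#' Share of repeated identical stimuli that evoked a supra-threshold burst:
#' with 4 repetitions the possible values are 0, 25, 50, 75, 100%.
#'
#' @param trials list of `reflex_event`s (or a logical vector of `occurred`
#'   flags) from one stimulus type.
#' @return percentage in [0, 100].
#' @export
reflex_occurrence <- function(trials) {
  if (!length(trials)) stop("no trials")
  occ <- if (is.logical(trials)) trials
         else vapply(trials, function(t) t$occurred, logical(1))
  100 * sum(occ) / length(occ)
}

#' Normalized RMS during a single-pulse stimulus
#'
#' RMS of the rectified EMG over the 0.8 s stimulation window, as a
#' percentage of the MVC reference.
#'
#' @param recording preprocessed (rectified) `emg_recording`.
#' @param muscle `"TA"` or `"SOL"`.
#' @param event schedule event row.
#' @param mvc an [mvc_reference()].
#' @param window stimulation window, seconds.
#' @return RMS in %MVC_RMS.
#' @export
single_pulse_rms <- function(recording, muscle = c("TA", "SOL"), event,
                             mvc, window = 0.8) {
  muscle <- match.arg(muscle)
  val <- rms(recording$channels[[muscle]], recording$times,
             event$onset, event$onset + window)
  100 * val / mvc$mvc_rms
}

#' EMG amplitude ratio of cyclic stimulation to rest
#'
#' RMS of the rectified EMG over the union of all stimulation windows of a
#' cyclic schedule, divided by the RMS over the pre-stimulation rest (5 s by
#' default, ending at the first event).
#'
#' @param recording preprocessed (rectified) `emg_recording`.
#' @param muscle `"TA"` or `"SOL"`.
#' @param schedule a cyclic `protocol_schedule`.
#' @param rest_window rest duration before the first event, seconds.
#' @return dimensionless ratio (>= 0); 1 means no change from rest.
#' @export
cyclic_rms_ratio <- function(recording, muscle = c("TA", "SOL"), schedule,
                             rest_window = 5) {
  muscle <- match.arg(muscle)
  if (!identical(schedule$kind, "cyclic")) {
    stop("cyclic_rms_ratio requires a cyclic schedule")
  }
  ev <- schedule$events
  first_onset <- min(ev$onset)
  if (first_onset - rest_window < recording$times[1] - 1e-9) {
    stop("recording lacks a ", rest_window, " s pre-stimulation rest")
  }
  x <- recording$channels[[muscle]]
  stim_idx <- sort(unique(unlist(lapply(seq_len(nrow(ev)), function(i) {
    window_idx(recording$times, ev$onset[i], ev$onset[i] + ev$duration[i])
  }))))
  rest <- rms(x, recording$times, first_onset - rest_window, first_onset)
  sqrt(mean(x[stim_idx]^2)) / rest
}

#' Flag trials with abnormally noisy baselines
#'
#' Automated stand-in for visual outlier screening: a trial is flagged when
#' its baseline SD exceeds `factor` times the session median baseline SD
#' (high background noise).
#'
#' @param baselines list of [baseline_stats()] for the session's trials.
#' @param factor multiple of the median SD above which a trial is excluded.
#' @return logical vector, TRUE = keep, FALSE = exclude.
#' @export
baseline_quality_flag <- function(baselines, factor = 5) {
  sds <- vapply(baselines, function(b) b$sd, numeric(1))
  sds <= factor * stats::median(sds)
}

#' Read / write EMG CSV files
#'
#' Columns `time,ta_uv,sol_uv,trigger`.
#'
#' @param path file path.
#' @param recording an `emg_recording`.
#' @return `read_emg_csv` returns an `emg_recording` in `raw` state; the
#'   writer returns the path invisibly.
#' @export
read_emg_csv <- function(path) {
  d <- utils::read.csv(path)
  emg_recording(d$time, d$ta_uv, d$sol_uv, d$trigger)
}

#' @rdname read_emg_csv
#' @export
write_emg_csv <- function(recording, path) {
  utils::write.csv(data.frame(time = recording$times,
                              ta_uv = recording$channels$TA,
                              sol_uv = recording$channels$SOL,
                              trigger = if (is.null(recording$trigger)) 0
                                        else recording$trigger),
                   path, row.names = FALSE)
  invisible(path)
}
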