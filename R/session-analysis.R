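# End-to-end analysis of a session: per-trial reflex detection and RMS over
# a schedule, and per-trial kinematic quantification.

#' Per-trial reflex detection and normalized RMS for a schedule
#'
#' Runs the full EMG chain over every scheduled event: preprocessing (if
#' needed), per-trial 0.8 s pre-stimulus baseline statistics, threshold +
#' duration reflex detection, and normalized RMS over the stimulation
#' window. Trials whose baseline SD exceeds 5x the session median are
#' flagged (`keep = FALSE`), replacing visual outlier screening.
#'
#' @param recording an `emg_recording` (raw recordings are preprocessed
#'   first).
#' @param schedule a `protocol_schedule`.
#' @param mvc named list of [mvc_reference()]s (`TA`, `SOL`).
#' @param muscles muscles to analyse.
#' @param stim_window analysis window after onset, seconds.
#' @param ... passed to [detect_reflex()].
#' @return data frame, one row per event x muscle: detection outcome,
#'   latency, peak and mean RMS in %MVC_RMS, baseline threshold and quality
#'   flag.
#' @export
analyze_single_pulse <- function(recording, schedule, mvc,
                                 muscles = c("TA", "SOL"),
                                 stim_window = 0.8, ...) {
  if (recording$state == "raw") recording <- preprocess_emg(recording)
  ev <- schedule$events
  rows <- list()
  for (m in muscles) {
    baselines <- lapply(seq_len(nrow(ev)), function(i) {
      baseline_stats(recording, m, ev$onset[i])
    })
    keep <- baseline_quality_flag(baselines)
    for (i in seq_len(nrow(ev))) {
      det <- detect_reflex(recording, m, ev[i, ], baseline = baselines[[i]],
                           mvc = mvc[[m]], window = min(ev$duration[i],
                                                        stim_window), ...)
      rows[[length(rows) + 1]] <- data.frame(
        trial = i, muscle = m, location = ev$location[i],
        pressure = ev$pressure[i], rise_speed = ev$rise_speed[i],
        occurred = det$occurred, onset_latency_s = det$onset_latency_s,
        peak_pct_mvc = det$peak_amplitude, double_burst = det$double_burst,
        rms_pct_mvc = single_pulse_rms(recording, m, ev[i, ], mvc[[m]],
                                       window = min(ev$duration[i],
                                                    stim_window)),
        threshold_uv = det$threshold_uv, keep = keep[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reflex occurrence by stimulus type
#'
#' @param trials output of [analyze_single_pulse()].
#' @param use_quality_flag drop trials flagged as noisy before scoring.
#' @return data frame with one row per muscle x location x rise speed x
#'   pressure and the occurrence percentage.
#' @export
occurrence_by_type <- function(trials, use_quality_flag = TRUE) {
  if (use_quality_flag) trials <- trials[trials$keep, , drop = FALSE]
  agg <- stats::aggregate(occurred ~ muscle + location + rise_speed + pressure,
                          data = trials,
                          FUN = function(o) 100 * sum(o) / length(o))
  names(agg)[names(agg) == "occurred"] <- "occurrence_pct"
  agg
}

#' Per-trial ankle-angle changes and perturbations
#'
#' For each scheduled event, extracts the marker segment from
#' `baseline_pad` s before onset to the event offset, computes the ankle
#' angle, smooths it (window-5 filter plus LOESS), and quantifies the
#' plate-induced change and any reflex-induced perturbation. The segment
#' ends at the event offset so the LOESS boundary does not mix the plateau
#' with the plate's retraction.
#'
#' Intended for single-pulse schedules, whose events are isolated. In a
#' cyclic schedule the heel and forefoot windows overlap by design
#' (mid-stance), so per-event changes superimpose both plates' excursions.
#'
#' @param markers a `marker_frames` object.
#' @param schedule a `protocol_schedule`.
#' @param baseline_pad seconds of baseline kept before each onset.
#' @param window,loess_span smoothing parameters, see [smooth_motion()].
#' @param convention angle convention, see [ankle_angle()].
#' @param threshold,min_duration perturbation criterion, see
#'   [detect_perturbation()].
#' @return data frame, one row per event: `change_deg`,
#'   `perturbation_detected`, `perturbation_magnitude_deg`, plus the event
#'   descriptors and the angle convention used.
#' @export
analyze_angle_changes <- function(markers, schedule, baseline_pad = 0.8,
                                  window = 5, loess_span = 0.1,
                                  convention = "interior",
                                  threshold = 0.5, min_duration = 0.05) {
  ev <- schedule$events
  theta_all <- ankle_angle(markers, convention = convention)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- window_idx(markers$times, ev$onset[i] - baseline_pad,
                      ev$onset[i] + ev$duration[i])
    seg <- structure(list(times = markers$times[idx],
                          theta_deg = theta_all$theta_deg[idx],
                          convention = convention, smoothed = FALSE),
                     class = "ankle_angle_series")
    seg <- smooth_motion(seg, window = window, loess_span = loess_span)
    res <- detect_perturbation(seg, ev[i, ], threshold = threshold,
                               min_duration = min_duration,
                               baseline_window = min(0.5, baseline_pad))
    data.frame(trial = i, location = ev$location[i],
               pressure = ev$pressure[i], rise_speed = ev$rise_speed[i],
               change_deg = res$plate_induced_change,
               perturbation_detected = res$perturbation_detected,
               perturbation_magnitude_deg = res$perturbation_magnitude,
               convention = convention)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
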