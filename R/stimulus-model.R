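# Pneumatic shoe-platform model: plate force amplitudes, trapezoidal force
# profiles, and the single-pulse / cyclic walking-like stimulation schedules.

#' Actuator geometry and rise times of a pressure plate
#'
#' Describes one pneumatic cylinder of the shoe platform. The heel plate is
#' driven by a 20 mm stroke, 32 mm bore cylinder and the forefoot plate by a
#' 10 mm stroke, 25 mm bore cylinder. Full extension takes 0.05 s for a fast
#' stimulus and 0.2 s (via a flow-control valve) for a slow stimulus.
#'
#' @param location `"heel"` or `"forefoot"`.
#' @param stroke_mm cylinder stroke in millimetres.
#' @param diameter_mm cylinder bore in millimetres.
#' @param rise_time_fast full-extension time of a fast stimulus, seconds.
#' @param rise_time_slow full-extension time of a slow stimulus, seconds.
#' @return an object of class `actuator_spec`.
#' @export
#' @examples
#' actuator_spec("heel")
actuator_spec <- function(location,
                          stroke_mm = if (location == "heel") 20 else 10,
                          diameter_mm = if (location == "heel") 32 else 25,
                          rise_time_fast = 0.05,
                          rise_time_slow = 0.2) {
  stopifnot_location(location)
  if (!(rise_time_fast > 0 && rise_time_slow > 0)) {
    stop("rise times must be positive")
  }
  if (rise_time_fast >= rise_time_slow) {
    stop("rise_time_fast must be shorter than rise_time_slow")
  }
  structure(list(location = location, stroke_mm = stroke_mm,
                 diameter_mm = diameter_mm,
                 rise_time_fast = rise_time_fast,
                 rise_time_slow = rise_time_slow),
            class = "actuator_spec")
}

#' Pressure-to-force calibration of the pressure plates
#'
#' Manufacturer's force amplitudes at the four tested pneumatic pressures.
#' The calibration is exactly linear: 80 N/bar on the heel and 50 N/bar on
#' the forefoot.
#'
#' @param entries data frame with columns `pressure_bar`, `heel_n`,
#'   `forefoot_n`; the default holds the four calibrated pressures
#'   2/2.5/3/3.5 bar.
#' @return an object of class `pressure_force_map`.
#' @export
pressure_force_map <- function(entries = data.frame(
                                 pressure_bar = c(2, 2.5, 3, 3.5),
                                 heel_n = c(160, 200, 240, 280),
                                 forefoot_n = c(100, 125, 150, 175))) {
  stopifnot(is.data.frame(entries),
            all(c("pressure_bar", "heel_n", "forefoot_n") %in% names(entries)))
  entries <- entries[order(entries$pressure_bar), , drop = FALSE]
  if (any(diff(entries$heel_n) <= 0) || any(diff(entries$forefoot_n) <= 0)) {
    stop("forces must strictly increase with pressure")
  }
  if (any(entries$heel_n <= entries$forefoot_n)) {
    stop("heel force must exceed forefoot force at equal pressure")
  }
  structure(list(entries = entries), class = "pressure_force_map")
}

#' Plate force amplitude at a given pneumatic pressure
#'
#' Looks up the commanded force for one plate; pressures between calibrated
#' rows are linearly interpolated. Extrapolation outside the calibrated range
#' is an error.
#'
#' @param location `"heel"` or `"forefoot"`.
#' @param pressure_bar pneumatic pressure in bar.
#' @param map a [pressure_force_map()].
#' @return force amplitude in newtons.
#' @export
#' @examples
#' force_amplitude("heel", 2)        # 160 N
#' force_amplitude("forefoot", 3.5)  # 175 N
force_amplitude <- function(location, pressure_bar,
                            map = pressure_force_map()) {
  stopifnot_location(location)
  e <- map$entries
  if (pressure_bar < min(e$pressure_bar) || pressure_bar > max(e$pressure_bar)) {
    stop("pressure ", pressure_bar, " bar outside calibrated range [",
         min(e$pressure_bar), ", ", max(e$pressure_bar), "]")
  }
  col <- if (location == "heel") e$heel_n else e$forefoot_n
  stats::approx(e$pressure_bar, col, xout = pressure_bar)$y
}

#' Trapezoidal plate force profile
#'
#' Commanded force over one stimulus: linear rise to the hold amplitude over
#' `rise_time`, hold, then linear fall over `fall_time`. The platform's
#' retraction speed is not separately controlled, so the fall defaults to the
#' rise time.
#'
#' @param amplitude_n hold force in newtons.
#' @param rise_time rise duration, seconds.
#' @param total_duration total stimulus duration, seconds.
#' @param fall_time fall duration, seconds; defaults to `rise_time`.
#' @param sample_rate samples per second of the output grid.
#' @param location plate the profile drives.
#' @return an object of class `force_profile` with `times` and `force`.
#' @export
#' @examples
#' p <- trapezoid_profile(280, 0.2, 0.8, sample_rate = 100)
#' max(p$force)  # 280
trapezoid_profile <- function(amplitude_n, rise_time, total_duration,
                              fall_time = rise_time, sample_rate = 1200,
                              location = "heel") {
  stopifnot(amplitude_n >= 0, rise_time >= 0, fall_time >= 0, sample_rate > 0)
  if (rise_time + fall_time > total_duration) {
    stop("rise_time + fall_time exceed total_duration: invalid geometry")
  }
  n <- round(total_duration * sample_rate) + 1
  times <- (seq_len(n) - 1) / sample_rate
  hold_end <- total_duration - fall_time
  force <- numeric(n)
  rising <- times < rise_time
  holding <- times >= rise_time & times <= hold_end
  falling <- times > hold_end
  if (rise_time > 0) force[rising] <- amplitude_n * times[rising] / rise_time
  force[holding] <- amplitude_n
  if (fall_time > 0) {
    force[falling] <- amplitude_n * (total_duration - times[falling]) / fall_time
  }
  force[n] <- 0
  force[1] <- if (rise_time == 0) amplitude_n else 0
  structure(list(times = times, force = force, location = location,
                 rise_time = rise_time, hold_amplitude = amplitude_n),
            class = "force_profile")
}

new_schedule <- function(events, kind, cycle_duration = NA_real_,
                         n_cycles = NA_integer_, lead_in_rest = 0) {
  events <- events[order(events$onset, events$location), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, kind = kind,
                 cycle_duration = cycle_duration, n_cycles = n_cycles,
                 lead_in_rest = lead_in_rest),
            class = "protocol_schedule")
}

#' Single-pulse stimulation schedule
#'
#' Full factorial of pressure, rise speed and plate location, each repeated
#' `reps` times and presented in a seeded random order, one stimulus per
#' `interval`. The defaults give the 16 stimulus types x 4 repetitions
#' protocol: 64 pulses of 0.8 s, one every 30 s.
#'
#' @param pressures pneumatic pressures in bar.
#' @param rise_speeds subset of `c("slow", "fast")`.
#' @param locations subset of `c("heel", "forefoot")`.
#' @param reps repetitions of each stimulus type.
#' @param interval seconds between consecutive stimulus onsets.
#' @param pulse_duration stimulus duration, seconds.
#' @param lead_in_rest rest before the first stimulus, seconds.
#' @param mid_session_break optional extra gap (seconds) inserted after half
#'   of the trials, mirroring the mid-session rest; 0 disables it.
#' @param seed integer seed for the presentation order; NULL uses the current
#'   RNG state.
#' @return a `protocol_schedule` of kind `"single_pulse"`.
#' @export
single_pulse_protocol <- function(pressures = c(2, 2.5, 3, 3.5),
                                  rise_speeds = c("slow", "fast"),
                                  locations = c("heel", "forefoot"),
                                  reps = 4, interval = 30,
                                  pulse_duration = 0.8,
                                  lead_in_rest = 5,
                                  mid_session_break = 0,
                                  seed = NULL) {
  if (!length(pressures) || !length(rise_speeds) || !length(locations)) {
    stop("pressures, rise_speeds and locations must all be non-empty")
  }
  stopifnot(reps >= 1, interval > pulse_duration)
  types <- expand.grid(pressure = pressures, rise_speed = rise_speeds,
                       location = locations, stringsAsFactors = FALSE)
  trials <- types[rep(seq_len(nrow(types)), each = reps), , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  onsets <- lead_in_rest + (seq_len(nrow(trials)) - 1) * interval
  if (mid_session_break > 0) {
    half <- ceiling(nrow(trials) / 2)
    onsets[(half + 1):length(onsets)] <-
      onsets[(half + 1):length(onsets)] + mid_session_break
  }
  events <- data.frame(onset = onsets, duration = pulse_duration,
                       location = trials$location, pressure = trials$pressure,
                       rise_speed = trials$rise_speed,
                       stringsAsFactors = FALSE)
  new_schedule(events, "single_pulse", lead_in_rest = lead_in_rest)
}

#' Cyclic walking-like loading schedule
#'
#' Emulates the plantar load of the stance phase: in each gait cycle of
#' duration T the heel plate is active over the first 40% and the forefoot
#' plate over 20--60%, so the two overlap for 20% of the cycle (mid-stance)
#' and the sole is unloaded for the remaining 40% (swing). Slow rise is used,
#' as in walking-load simulation.
#'
#' @param cycle_duration gait-cycle duration T in seconds (2 s short cycle,
#'   5 s long cycle).
#' @param pressure pneumatic pressure in bar.
#' @param n_cycles number of cycles (strikes).
#' @param lead_in_rest rest before the first cycle, seconds.
#' @param rise_speed plate rise speed; the walking simulation uses `"slow"`.
#' @return a `protocol_schedule` of kind `"cyclic"`.
#' @export
#' @examples
#' s <- cyclic_protocol(5, 3.5, n_cycles = 9, lead_in_rest = 5)
#' head(s$events)  # heel 5-7 s, forefoot 6-8 s, ...
cyclic_protocol <- function(cycle_duration, pressure = 3.5, n_cycles = 9,
                            lead_in_rest = 5, rise_speed = "slow") {
  stopifnot(cycle_duration > 0, n_cycles >= 1, lead_in_rest >= 0)
  k <- rep(seq_len(n_cycles) - 1, each = 2)
  loc <- rep(c("heel", "forefoot"), n_cycles)
  onset <- lead_in_rest + k * cycle_duration +
    ifelse(loc == "forefoot", 0.2 * cycle_duration, 0)
  events <- data.frame(onset = onset, duration = 0.4 * cycle_duration,
                       location = loc, pressure = pressure,
                       rise_speed = rise_speed, stringsAsFactors = FALSE)
  new_schedule(events, "cyclic", cycle_duration = cycle_duration,
               n_cycles = as.integer(n_cycles), lead_in_rest = lead_in_rest)
}

#' Walking speed corresponding to a simulated gait cycle
#'
#' A gait cycle covers two steps, so speed = 2 x step length / cycle
#' duration, converted to km/h. For a 0.85 m step, the 5 s and 2 s cycles
#' correspond to about 1.2 and 3.0 km/h.
#'
#' @param cycle_duration gait-cycle duration, seconds.
#' @param step_length step length, metres.
#' @return speed in km/h.
#' @export
walking_speed <- function(cycle_duration, step_length = 0.85) {
  stopifnot(cycle_duration > 0, step_length > 0)
  2 * step_length / cycle_duration * 3.6
}

#' Binary trigger traces for a schedule
#'
#' One 0/1 series per plate, high while that plate's stimulus is active,
#' mirroring the trigger channel saved alongside the EMG.
#'
#' @param schedule a `protocol_schedule`.
#' @param sample_rate samples per second.
#' @param total_duration length of the traces, seconds; defaults to the end
#'   of the last event plus the lead-in rest.
#' @return data frame with columns `time`, `heel`, `forefoot`.
#' @export
trigger_trace <- function(schedule, sample_rate = 1200,
                          total_duration = NULL) {
  ev <- schedule$events
  end_needed <- if (nrow(ev)) max(ev$onset + ev$duration) else 0
  if (is.null(total_duration)) {
    total_duration <- end_needed + schedule$lead_in_rest
  }
  if (total_duration < end_needed) {
    stop("total_duration ", total_duration,
         " s does not cover the schedule (needs ", end_needed, " s)")
  }
  n <- round(total_duration * sample_rate)
  time <- (seq_len(n) - 1) / sample_rate
  out <- data.frame(time = time, heel = 0, forefoot = 0)
  for (i in seq_len(nrow(ev))) {
    idx <- window_idx(time, ev$onset[i], ev$onset[i] + ev$duration[i])
    out[[ev$location[i]]][idx] <- 1
  }
  out
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat("<protocol_schedule> kind:", x$kind, "-", nrow(x$events), "events\n")
  if (identical(x$kind, "cyclic")) {
    cat("  cycle:", x$cycle_duration, "s x", x$n_cycles,
        "cycles, lead-in rest", x$lead_in_rest, "s\n")
  }
  print(utils::head(x$events, 6))
  if (nrow(x$events) > 6) cat("  ...", nrow(x$events) - 6, "more\n")
  invisible(x)
}

#' Write / read a schedule as JSON
#'
#' @param schedule a `protocol_schedule`.
#' @param path file path.
#' @return `read_schedule_json` returns a `protocol_schedule`;
#'   `write_schedule_json` returns `path` invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(kind = schedule$kind,
              cycle_duration = schedule$cycle_duration,
              n_cycles = schedule$n_cycles,
              lead_in_rest = schedule$lead_in_rest,
              events = schedule$events)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_schedule(as.data.frame(obj$events), obj$kind,
               cycle_duration = if (is.null(obj$cycle_duration)) NA_real_ else obj$cycle_duration,
               n_cycles = if (is.null(obj$n_cycles)) NA_integer_ else obj$n_cycles,
               lead_in_rest = obj$lead_in_rest)
}
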