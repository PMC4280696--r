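# Sagittal ankle kinematics from three markers: segment lengths, the
# shank-foot angle by the law of cosines, two-stage motion smoothing, and
# quantification of plate-induced angle changes and reflex perturbations.

#' Marker frame series
#'
#' Sagittal-plane (x forward, y up, metres) trajectories of the three
#' markers used for ankle-angle computation: medial knee joint, medial ankle
#' joint and first metatarsal head, sampled on a uniform grid (100 Hz in the
#' recordings this models).
#'
#' @param times sample times, seconds (uniform grid).
#' @param knee,ankle,metatarsal two-column matrices (x, y) in metres, one row
#'   per frame.
#' @return an object of class `marker_frames`.
#' @export
marker_frames <- function(times, knee, ankle, metatarsal) {
  knee <- as.matrix(knee); ankle <- as.matrix(ankle)
  metatarsal <- as.matrix(metatarsal)
  n <- length(times)
  stopifnot(nrow(knee) == n, nrow(ankle) == n, nrow(metatarsal) == n,
            ncol(knee) == 2, ncol(ankle) == 2, ncol(metatarsal) == 2)
  if (n > 1) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) stop("non-uniform sampling")
  }
  structure(list(times = times, knee = knee, ankle = ankle,
                 metatarsal = metatarsal),
            class = "marker_frames")
}

#' Shank, foot and knee-metatarsal segment lengths
#'
#' Euclidean distances between the marker pairs: knee-ankle (shank), ankle-
#' metatarsal (foot) and knee-metatarsal, per frame.
#'
#' @param frames a [marker_frames()] object.
#' @return data frame with columns `L_ka`, `L_am`, `L_km` (metres).
#' @export
segment_lengths <- function(frames) {
  d <- function(a, b) sqrt(rowSums((a - b)^2))
  out <- data.frame(L_ka = d(frames$knee, frames$ankle),
                    L_am = d(frames$ankle, frames$metatarsal),
                    L_km = d(frames$knee, frames$metatarsal))
  if (any(out$L_ka <= 0) || any(out$L_am <= 0) || any(out$L_km <= 0)) {
    stop("coincident markers: degenerate geometry")
  }
  out
}

#' Sagittal ankle angle from the three markers
#'
#' The angle at the ankle between the shank and the dorsum of the foot, via
#' the law of cosines on the three segment lengths. Dorsiflexion (metatarsal
#' moving toward the knee) decreases the angle; plantarflexion increases it.
#' The neutral supine posture is approximately 150 degrees.
#'
#' Two conventions are offered. `"interior"` (default) reports the interior
#' triangle angle `acos((L_ka^2 + L_am^2 - L_km^2) / (2 L_ka L_am))`, which
#' matches the reported neutral posture. `"printed_offset"` adds 180 degrees,
#' following the literal published formula; it is retained so that either
#' convention can be reproduced, and the choice is recorded in the result.
#'
#' @param frames a [marker_frames()] object.
#' @param convention `"interior"` or `"printed_offset"`.
#' @param tol tolerance for clipping the arc-cosine argument to [-1, 1].
#' @return an object of class `ankle_angle_series` with `times`,
#'   `theta_deg`, `convention` and `smoothed` fields.
#' @export
ankle_angle <- function(frames, convention = c("interior", "printed_offset"),
                        tol = 1e-9) {
  convention <- match.arg(convention)
  L <- segment_lengths(frames)
  arg <- (L$L_ka^2 + L$L_am^2 - L$L_km^2) / (2 * L$L_ka * L$L_am)
  if (any(abs(arg) > 1 + tol)) {
    stop("arc-cosine argument outside [-1, 1]: inconsistent marker geometry")
  }
  arg <- pmin(1, pmax(-1, arg))
  theta <- acos(arg) * 180 / pi
  if (convention == "printed_offset") theta <- theta + 180
  structure(list(times = frames$times, theta_deg = theta,
                 convention = convention, smoothed = FALSE),
            class = "ankle_angle_series")
}

#' @export
print.ankle_angle_series <- function(x, ...) {
  cat("<ankle_angle_series>", length(x$times), "frames,",
      "convention:", x$convention,
      if (x$smoothed) "(smoothed)" else "(raw)", "\n")
  cat("  theta range:", round(range(x$theta_deg), 2), "deg\n")
  invisible(x)
}

# Centered moving average preserving length; edges use the partial window.
moving_average <- function(x, window) {
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Two-stage smoothing of a motion trace
#'
#' Stage one removes sample noise with a window-5 filter (centered moving
#' average by default, running median as an option); stage two applies LOESS
#' local linear regression. Output length equals input length.
#'
#' @param series an `ankle_angle_series`, or a numeric vector with `times`
#'   supplied.
#' @param window odd window length (samples) of the first-stage filter.
#' @param loess_span LOESS span as a fraction of the series; 0 skips stage 2.
#' @param stat first-stage statistic, `"mean"` or `"median"`.
#' @param times sample times when `series` is a bare numeric vector.
#' @return object of the same shape as `series`, smoothed.
#' @export
smooth_motion <- function(series, window = 5, loess_span = 0.1,
                          stat = c("mean", "median"), times = NULL) {
  stat <- match.arg(stat)
  stopifnot(window >= 1, window %% 2 == 1, loess_span <= 1)
  is_series <- inherits(series, "ankle_angle_series")
  x <- if (is_series) series$theta_deg else as.numeric(series)
  tt <- if (is_series) series$times else times
  if (is.null(tt)) tt <- seq_along(x)
  if (length(x) < window) stop("series shorter than the smoothing window")
  y <- if (window == 1) x
       else if (stat == "mean") moving_average(x, window)
       else stats::runmed(x, window, endrule = "keep")
  if (loess_span > 0 && stats::var(y) > 0) {
    fit <- stats::loess(y ~ tt, span = loess_span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    y <- stats::predict(fit, tt)
  }
  if (is_series) {
    series$theta_deg <- y
    series$smoothed <- TRUE
    series
  } else y
}

#' Plate-induced ankle-angle change for one stimulus
#'
#' Mean angle over a plateau window ending at the event offset minus the mean
#' over a baseline window immediately before onset. Negative changes indicate
#' dorsiflexion (heel plate), positive plantarflexion (forefoot plate). The
#' plateau default (final 0.2 s of the stimulus) excludes the plate's rise.
#'
#' @param angle_series an `ankle_angle_series`.
#' @param event one row of a schedule's `events` (list or 1-row data frame
#'   with `onset` and `duration`).
#' @param baseline_window seconds of baseline before onset.
#' @param plateau_window seconds at the end of the event used as the plateau.
#' @return signed change in degrees.
#' @export
plate_induced_change <- function(angle_series, event,
                                 baseline_window = 0.5,
                                 plateau_window = 0.2) {
  onset <- event$onset; offset <- event$onset + event$duration
  tt <- angle_series$times
  base <- window_idx(tt, onset - baseline_window, onset)
  plat <- window_idx(tt, offset - plateau_window, offset)
  mean(angle_series$theta_deg[plat]) - mean(angle_series$theta_deg[base])
}

#' Detect a reflex-induced ankle perturbation
#'
#' Fits the idealized plate response (baseline level, linear ramp over the
#' plate rise time, hold at the plateau level) and inspects the residual
#' during the stimulus. A perturbation is flagged when the residual exceeds
#' `threshold` in absolute value for at least `min_duration`; a 1 degree
#' excursion, the size reported for strong withdrawal-like reflexes, is then
#' unambiguously detected while smoothing residuals are not.
#'
#' @param angle_series an `ankle_angle_series` (ideally smoothed).
#' @param event schedule event row (`onset`, `duration`, optionally
#'   `rise_speed`).
#' @param rise_time plate rise time, seconds; taken from `event$rise_speed`
#'   (0.05 fast / 0.2 slow) when available.
#' @param threshold residual magnitude that counts as a perturbation, degrees.
#' @param min_duration minimum supra-threshold duration, seconds.
#' @param baseline_window,plateau_window as in [plate_induced_change()].
#' @return list with `perturbation_detected`, `perturbation_magnitude`
#'   (degrees, 0 when none) and `plate_induced_change` (degrees).
#' @export
detect_perturbation <- function(angle_series, event, rise_time = NULL,
                                threshold = 0.5, min_duration = 0.05,
                                baseline_window = 0.5, plateau_window = 0.2) {
  if (is.null(rise_time)) {
    rise_time <- if (!is.null(event$rise_speed) &&
                     identical(as.character(event$rise_speed), "fast")) 0.05 else 0.2
  }
  tt <- angle_series$times
  onset <- event$onset; offset <- event$onset + event$duration
  base <- mean(angle_series$theta_deg[window_idx(tt, onset - baseline_window, onset)])
  plat <- mean(angle_series$theta_deg[window_idx(tt, offset - plateau_window, offset)])
  idx <- window_idx(tt, onset, offset)
  rel <- tt[idx] - onset
  ideal <- base + (plat - base) * pmin(1, rel / rise_time)
  resid <- angle_series$theta_deg[idx] - ideal
  dt <- tt[2] - tt[1]
  need <- max(1L, round(min_duration / dt))
  r <- rle(abs(resid) > threshold)
  hit <- any(r$values & r$lengths >= need)
  list(perturbation_detected = hit,
       perturbation_magnitude = if (hit) max(abs(resid)) else 0,
       plate_induced_change = plat - base)
}

#' Read / write marker and angle CSV files
#'
#' Marker files have columns `time,xk,yk,xa,ya,xm,ym` (SI units); angle files
#' have `time,theta_deg`.
#'
#' @param path file path.
#' @param frames a [marker_frames()] object.
#' @param series an `ankle_angle_series`.
#' @return `read_markers_csv` returns a `marker_frames`; writers return the
#'   path invisibly.
#' @export
read_markers_csv <- function(path) {
  d <- utils::read.csv(path)
  marker_frames(d$time, cbind(d$xk, d$yk), cbind(d$xa, d$ya),
                cbind(d$xm, d$ym))
}

#' @rdname read_markers_csv
#' @export
write_markers_csv <- function(frames, path) {
  utils::write.csv(data.frame(time = frames$times,
                              xk = frames$knee[, 1], yk = frames$knee[, 2],
                              xa = frames$ankle[, 1], ya = frames$ankle[, 2],
                              xm = frames$metatarsal[, 1],
                              ym = frames$metatarsal[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_markers_csv
#' @export
write_angles_csv <- function(series, path) {
  utils::write.csv(data.frame(time = series$times,
                              theta_deg = series$theta_deg),
                   path, row.names = FALSE)
  invisible(path)
}
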