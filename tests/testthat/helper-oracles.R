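# Independent oracles and constructors used across tests.

# Upper-tail Student-t probability by numerical integration of the density,
# independent of pt().
t_upper_tail_numint <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, lower = t, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# A rectified recording built directly from a non-negative sample vector
# (state "rectified" so detection functions accept it).
rectified_recording <- function(x, fs = 1200) {
  emg_recording((seq_along(x) - 1) / fs, x, x, state = "rectified")
}

# Ankle-angle series from a plain numeric trace.
angle_series <- function(theta, fs = 100) {
  structure(list(times = (seq_along(theta) - 1) / fs, theta_deg = theta,
                 convention = "interior", smoothed = FALSE),
            class = "ankle_angle_series")
}

# Marker frame with the metatarsal placed so the interior shank-foot angle
# is exactly `theta_deg`; knee above the ankle.
frame_at_angle <- function(theta_deg, l_shank = 0.4, l_foot = 0.15) {
  az <- (90 - theta_deg) * pi / 180
  marker_frames(0,
                knee = cbind(0, l_shank),
                ankle = cbind(0, 0),
                metatarsal = cbind(l_foot * cos(az), l_foot * sin(az)))
}

default_mvc_refs <- function() {
  list(TA = mvc_reference_from_value("TA", 189.16),
       SOL = mvc_reference_from_value("SOL", 68.89))
}
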