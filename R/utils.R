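# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for report tables: exact halves move away from zero
#' (e.g. 189.155 -> 189.16 at 2 digits), unlike [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Half-open sample window [start_s, end_s) on a uniform grid starting at
# times[1]; returns integer indices, validating coverage.
window_idx <- function(times, start_s, end_s) {
  if (length(times) < 2) stop("time grid too short")
  dt <- times[2] - times[1]
  i0 <- round((start_s - times[1]) / dt) + 1
  i1 <- round((end_s - times[1]) / dt)
  if (i0 < 1 || i1 > length(times) || i1 < i0) {
    stop("requested window [", start_s, ", ", end_s, ") outside recording")
  }
  i0:i1
}

stopifnot_location <- function(location) {
  if (!location %in% c("heel", "forefoot")) {
    stop("location must be 'heel' or 'forefoot', got '", location, "'")
  }
  location
}
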