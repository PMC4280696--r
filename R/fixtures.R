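# Bundled reference dataset: per-subject summary values from an evaluation
# of the pneumatic shoe platform in ten able-bodied supine subjects.

#' Bundled per-subject reference tables
#'
#' Per-subject summary values from a study of mechanical foot-sole
#' stimulation in ten able-bodied supine subjects, shipped with the package
#' as reference data for the aggregation and testing functions:
#'
#' * `rest_mvc_uv` — rectified RMS EMG at rest and during maximal voluntary
#'   contraction, microvolts, for TA and SOL.
#' * `slow_rms_pct` — mean RMS EMG during slow (0.2 s rise) single-pulse
#'   stimuli at 3.5 bar, %MVC_RMS, by plate location and muscle.
#' * `fast_rms_pct` — the same for fast (0.05 s rise) stimuli.
#' * `angle_change_deg` — plate-induced ankle-angle change, degrees
#'   (negative = dorsiflexion from heel loading).
#' * `reflex_occurrence_pct` — reflex occurrence (%) over four repetitions
#'   per stimulus type, by muscle, speed and location.
#'
#' @param name one of the table names above.
#' @return data frame with a `subject` column and per-condition columns.
#' @export
#' @examples
#' aggregate_subjects(reference_table("slow_rms_pct")$heel_ta)$mean_2dp
reference_table <- function(name = c("rest_mvc_uv", "slow_rms_pct",
                                     "fast_rms_pct", "angle_change_deg",
                                     "reflex_occurrence_pct")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "solereflex", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ord <- order(as.integer(sub("^S", "", d$subject)))
  d[ord, , drop = FALSE]
}
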