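# Per-subject aggregation, paired one-sided t-tests and report emission.

#' Aggregate per-subject values into a Mean +/- SD row
#'
#' Sample mean and SD (n - 1 denominator) over subjects, with display values
#' rounded half-away-from-zero to 2 decimals as in the summary tables.
#'
#' @param values numeric vector, one value per subject.
#' @param condition,muscle optional labels carried into the row.
#' @return list with `mean`, `sd`, `n` (full precision) and `mean_2dp`,
#'   `sd_2dp` (display rounding).
#' @export
#' @examples
#' aggregate_subjects(c(0.91, 0.46, 1.19, 3.21, 1.70,
#'                      4.41, 2.89, 1.51, 1.38, 3.50))$mean_2dp  # 2.12
aggregate_subjects <- function(values, condition = NA, muscle = NA) {
  if (length(values) < 2) stop("need at least two subjects for a SD")
  m <- mean(values); s <- stats::sd(values)
  list(condition = condition, muscle = muscle,
       mean = m, sd = s, n = length(values),
       mean_2dp = round_half_away(m, 2), sd_2dp = round_half_away(s, 2))
}

#' Paired one-sided t-test (fast > slow)
#'
#' Tests whether fast-rising stimuli produce higher per-subject responses
#' than slow ones: on differences d = fast - slow,
#' t = mean(d) / (sd(d) / sqrt(n)) with n - 1 degrees of freedom, and p is
#' the upper-tail Student-t probability.
#'
#' @param slow,fast equal-length per-subject value vectors, paired by
#'   subject.
#' @return an object of class `paired_test` with `t`, `df`, `p`,
#'   `direction`.
#' @export
paired_t_one_sided <- function(slow, fast) {
  if (length(slow) != length(fast)) stop("paired vectors differ in length")
  n <- length(slow)
  if (n < 2) stop("need at least two pairs")
  d <- fast - slow
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero difference variance: t-test undefined")
  t <- mean(d) / (sdd / sqrt(n))
  structure(list(t = t, df = n - 1,
                 p = stats::pt(t, df = n - 1, lower.tail = FALSE),
                 direction = "greater"),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Paired one-sided t-test (fast > slow): t = %.3f, df = %d, p = %.4f\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Significance at a fixed alpha
#'
#' @param result a [paired_t_one_sided()] result.
#' @param alpha significance level; the convention is strict (p = alpha is
#'   not significant).
#' @return logical flag.
#' @export
significance_flag <- function(result, alpha = 0.05) {
  result$p < alpha
}

#' Build the summary report from per-subject tables
#'
#' Takes per-subject condition tables (data frames with a `subject` column
#' and one column per condition-muscle) and optional paired comparisons, and
#' writes per-table CSVs (subject rows, a Mean +/- SD row, and a p-value row
#' where a comparison applies) plus one machine-readable JSON of all
#' aggregates and tests. Subjects are sorted for deterministic output.
#'
#' @param summaries named list of data frames; each must contain `subject`.
#' @param tests named list of comparisons, each a list with `table_slow`,
#'   `table_fast` (names in `summaries`) whose shared value columns are
#'   tested column-by-column (fast > slow).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the report structure (aggregates and tests).
#' @export
build_report <- function(summaries, tests = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- lapply(summaries, function(d) sort(d$subject))
  ref <- subjects[[1]]
  for (nm in names(summaries)) {
    if (!identical(subjects[[nm]], ref)) {
      stop("subject sets differ across tables: ", names(summaries)[1],
           " vs ", nm, " (",
           paste(union(setdiff(ref, subjects[[nm]]),
                       setdiff(subjects[[nm]], ref)), collapse = ", "), ")")
    }
  }
  report <- list(tables = list(), tests = list())
  for (nm in names(summaries)) {
    d <- summaries[[nm]][order(summaries[[nm]]$subject), , drop = FALSE]
    vcols <- setdiff(names(d), "subject")
    aggs <- lapply(vcols, function(cn) aggregate_subjects(d[[cn]], nm, cn))
    names(aggs) <- vcols
    report$tables[[nm]] <- aggs
    disp <- d
    disp$subject <- as.character(disp$subject)
    msd <- vapply(vcols, function(cn) {
      sprintf("%.2f ± %.2f", aggs[[cn]]$mean_2dp, aggs[[cn]]$sd_2dp)
    }, character(1))
    disp <- rbind(disp, c("Mean ± SD", msd))
    utils::write.csv(disp, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(tests)) {
    cmp <- tests[[nm]]
    ds <- summaries[[cmp$table_slow]]; df_ <- summaries[[cmp$table_fast]]
    ds <- ds[order(ds$subject), ]; df_ <- df_[order(df_$subject), ]
    vcols <- intersect(setdiff(names(ds), "subject"),
                       setdiff(names(df_), "subject"))
    res <- lapply(vcols, function(cn) {
      r <- paired_t_one_sided(ds[[cn]], df_[[cn]])
      list(column = cn, t = r$t, df = r$df, p = r$p,
           significant = significance_flag(r))
    })
    names(res) <- vcols
    report$tests[[nm]] <- res
    prow <- data.frame(column = vcols,
                       p = vapply(res, function(r) r$p, numeric(1)),
                       t = vapply(res, function(r) r$t, numeric(1)),
                       significant = vapply(res, function(r) r$significant,
                                            logical(1)))
    utils::write.csv(prow, file.path(out_dir, paste0(nm, "_tests.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
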