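# Longitudinal analytics over the 8-week, three-sessions-a-day design:
# weeks -4..-1 are baseline, weeks 1..4 treatment. All operations work on the
# side-averaged metric-record table (one value per subject, day, timepoint,
# metric) and never impute: incomplete days are skipped and reported.

TP_PAIRS <- list(c("morning_wake", "morning_wash"),
                 c("morning_wake", "evening_wash"),
                 c("morning_wash", "evening_wash"))

subset_metric <- function(records, metric) {
  records <- metric_records(records)
  metric <- match.arg(metric, METRICS)
  rec <- records[records$metric == metric, , drop = FALSE]
  if (anyNA(rec$face_side) && any(!is.na(rec$face_side)))
    stop("mixed side-averaged and per-side records; run average_sides() first")
  if (any(!is.na(rec$face_side))) rec <- average_sides(rec)
  key <- paste(rec$subject_id, rec$study_day, rec$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, day, timepoint) after side-averaging")
  rec
}

#' Delta fluctuation of a day's three timepoint values
#'
#' The paper's within-day fluctuation summary: highest minus lowest value
#' among the three daily sessions. Translation-invariant and nonnegative.
#'
#' @param values numeric vector of exactly three values (one per timepoint).
#' @return `max(values) - min(values)`.
#' @export
delta_fluctuation <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 3L || anyNA(values))
    stop("delta_fluctuation needs a complete triple of three values")
  max(values) - min(values)
}

#' Per-day delta fluctuation table
#'
#' Computes [delta_fluctuation()] for every complete subject-day of one
#' metric. Days with fewer than three timepoints are skipped, never imputed;
#' the skipped (subject, day) pairs are attached as the `"incomplete"`
#' attribute (the completeness report).
#'
#' @param records metric-record data frame.
#' @param metric one of `"pore_area"`, `"roughness"`, `"redness"`.
#' @return data frame `subject_id, study_day, week_index, delta` with
#'   attribute `incomplete`.
#' @export
delta_fluctuation_table <- function(records, metric) {
  rec <- subset_metric(records, metric)
  sp <- split(rec, list(rec$subject_id, rec$study_day), drop = TRUE)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < 3L) return(NULL)
    data.frame(subject_id = d$subject_id[1], study_day = d$study_day[1],
               week_index = d$week_index[1],
               delta = max(d$value_au) - min(d$value_au))
  })
  incomplete <- do.call(rbind, lapply(sp[vapply(rows, is.null, logical(1))],
    function(d) data.frame(subject_id = d$subject_id[1],
                           study_day = d$study_day[1],
                           n_present = nrow(d))))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(subject_id = character(0), study_day = integer(0),
                      week_index = integer(0), delta = numeric(0))
  out <- out[order(out$subject_id, out$study_day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "incomplete") <- incomplete
  out
}

#' Weekly average table
#'
#' For each (week, timepoint) cell: the mean of each subject's available days
#' in that week, then the unweighted grand mean over subjects (so subjects
#' with unequal day counts weigh equally). Cell subject counts are reported;
#' empty cells are `NA`.
#'
#' @param records metric-record data frame.
#' @param metric metric name.
#' @return data frame `week_index, timepoint, mean_au, n_subjects`.
#' @export
weekly_average <- function(records, metric) {
  rec <- subset_metric(records, metric)
  weeks <- c(-4:-1, 1:4)
  grid <- expand.grid(week_index = weeks, timepoint = TIMEPOINTS,
                      stringsAsFactors = FALSE)
  subj_means <- stats::aggregate(
    value_au ~ subject_id + week_index + timepoint, data = rec, FUN = mean)
  cells <- stats::aggregate(value_au ~ week_index + timepoint,
                            data = subj_means, FUN = mean)
  counts <- stats::aggregate(value_au ~ week_index + timepoint,
                             data = subj_means, FUN = length)
  names(cells)[3] <- "mean_au"
  names(counts)[3] <- "n_subjects"
  out <- merge(merge(grid, cells, all.x = TRUE), counts, all.x = TRUE)
  out$n_subjects[is.na(out$n_subjects)] <- 0L
  out <- out[order(out$week_index, match(out$timepoint, TIMEPOINTS)), ]
  rownames(out) <- NULL
  out
}

# per-subject mean value over a week subset, one column per timepoint
subject_timepoint_means <- function(rec, weeks) {
  rec <- rec[rec$week_index %in% weeks, , drop = FALSE]
  if (!nrow(rec)) return(NULL)
  agg <- stats::aggregate(value_au ~ subject_id + timepoint, data = rec,
                          FUN = mean)
  stats::reshape(agg, idvar = "subject_id", timevar = "timepoint",
                 direction = "wide")
}

#' Baseline comparison of the three daily timepoints
#'
#' Over the baseline period (weeks -4..-1), averages each subject's values
#' per timepoint, then runs a paired Wilcoxon signed-rank test for each of
#' the three timepoint pairs, Holm-adjusted across the three tests.
#'
#' @param records metric-record data frame.
#' @param metric metric name.
#' @param adjust apply Holm adjustment (default TRUE).
#' @return list of three [comparison_result()]s, labelled by pair.
#' @export
compare_timepoints_baseline <- function(records, metric, adjust = TRUE) {
  rec <- subset_metric(records, metric)
  wide <- subject_timepoint_means(rec, -4:-1)
  cols <- paste0("value_au.", TIMEPOINTS)
  if (is.null(wide) || !all(cols %in% names(wide)))
    stop("insufficient data: need baseline records at all three timepoints")
  complete <- wide[stats::complete.cases(wide[cols]), , drop = FALSE]
  if (nrow(complete) < 6L)
    stop("insufficient data: ", nrow(complete),
         " subjects with complete baseline pairs (need >= 6)")
  res <- lapply(TP_PAIRS, function(pr) {
    r <- wilcoxon_signed_rank(complete[[paste0("value_au.", pr[1])]],
                              complete[[paste0("value_au.", pr[2])]])
    r$label <- paste(pr[1], "vs", pr[2])
    r
  })
  if (adjust) res <- holm_adjust(res)
  names(res) <- vapply(res, function(r) r$label, character(1))
  res
}

#' Treatment-effect comparisons
#'
#' Per timepoint, a paired Wilcoxon signed-rank test of subject means in
#' week 4 against the baseline reference (week -4 by default, or the pooled
#' baseline weeks), plus a paired test of subject-mean delta fluctuation over
#' the whole treatment period against the whole baseline period.
#'
#' @param records metric-record data frame.
#' @param metric metric name.
#' @param baseline `"week-4"` (the default, week index -4) or `"pooled"`
#'   (weeks -4..-1 averaged).
#' @return named list of four [comparison_result()]s (three timepoints plus
#'   `delta_fluctuation`).
#' @export
treatment_effect <- function(records, metric,
                             baseline = c("week-4", "pooled")) {
  baseline <- match.arg(baseline)
  rec <- subset_metric(records, metric)
  base_weeks <- if (baseline == "pooled") -4:-1 else -4L
  wb <- subject_timepoint_means(rec, base_weeks)
  wt <- subject_timepoint_means(rec, 4L)
  if (is.null(wb) || is.null(wt))
    stop("insufficient data: need both baseline and week-4 records")
  res <- list()
  for (tp in TIMEPOINTS) {
    col <- paste0("value_au.", tp)
    if (!col %in% names(wb) || !col %in% names(wt))
      stop("insufficient data: timepoint ", tp, " missing in a period")
    m <- merge(wb[c("subject_id", col)], wt[c("subject_id", col)],
               by = "subject_id", suffixes = c(".base", ".treat"))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 6L)
      stop("insufficient data: ", nrow(m), " paired subjects at ", tp)
    r <- wilcoxon_signed_rank(m[[paste0(col, ".treat")]],
                              m[[paste0(col, ".base")]])
    r$label <- paste0(tp, " week4 vs ", baseline)
    res[[tp]] <- r
  }
  dt <- delta_fluctuation_table(rec, metric)
  dt$period <- ifelse(dt$week_index < 0, "base", "treat")
  agg <- stats::aggregate(delta ~ subject_id + period, data = dt, FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject_id", timevar = "period",
                         direction = "wide")
  if (!all(c("delta.base", "delta.treat") %in% names(wide)))
    stop("insufficient data: need delta fluctuation in both periods")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 6L)
    stop("insufficient data: ", nrow(wide),
         " subjects with delta fluctuation in both periods")
  r <- wilcoxon_signed_rank(wide$delta.treat, wide$delta.base)
  r$label <- "delta_fluctuation treatment vs baseline"
  res$delta_fluctuation <- r
  res
}

#' Between-study comparison
#'
#' Welch's t-test (unpaired, unequal variances) on the subject baseline
#' means of two independent cohorts.
#'
#' @param records_a,records_b metric-record tables of the two studies.
#' @param metric metric name.
#' @return a [comparison_result()].
#' @export
compare_studies <- function(records_a, records_b, metric) {
  subj_base <- function(records) {
    rec <- subset_metric(records, metric)
    rec <- rec[rec$week_index < 0, , drop = FALSE]
    if (!nrow(rec)) stop("insufficient data: no baseline records")
    agg <- stats::aggregate(value_au ~ subject_id, data = rec, FUN = mean)
    agg$value_au
  }
  a <- subj_base(records_a)
  b <- subj_base(records_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("insufficient data: need >= 3 subjects per study, got ",
         length(a), " and ", length(b))
  r <- welch_t(a, b)
  r$label <- paste("study A vs study B,", metric, "baseline")
  r
}
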