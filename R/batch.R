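# Batch orchestration: run calibration and the three metrics over a
# directory of session images described by a sidecar CSV (columns: file,
# subject_id, study_day, timepoint, face_side), side-average, and emit one
# metric-record row per (session, metric), plus a per-image QC log.

#' Analyze a batch of session images
#'
#' For every sidecar row: read the image, measure the gray tip, calibrate,
#' score pore area, roughness and redness at the configured ROIs. Left/right
#' half-face values of one session are averaged into a single record per
#' metric. Missing files are skipped (and listed); a malformed sidecar row is
#' a hard error naming the row. The fully-resolved configuration is written
#' next to the outputs.
#'
#' @param image_dir directory holding the images.
#' @param sidecar_csv path to the sidecar CSV (or a data frame).
#' @param config a configuration list from [load_config()].
#' @param out_dir output directory; default `image_dir`. Receives
#'   `metrics.csv`, `qc_log.csv` and `config.resolved.yaml`.
#' @return list with `records` (metric-record data frame), `qc` (per-image
#'   QC data frame), `skipped` (character vector of missing files) and
#'   `status` (0 clean, 2 completed with skips).
#' @export
analyze_batch <- function(image_dir, sidecar_csv, config = default_config(),
                          out_dir = image_dir) {
  sidecar <- if (is.data.frame(sidecar_csv)) sidecar_csv
             else utils::read.csv(sidecar_csv, stringsAsFactors = FALSE,
                                  colClasses = c(subject_id = "character"))
  need <- c("file", "subject_id", "study_day", "timepoint", "face_side")
  if (!nrow(sidecar)) stop("empty sidecar: no images to analyze")
  if (!all(need %in% names(sidecar)))
    stop("sidecar lacks columns: ",
         paste(setdiff(need, names(sidecar)), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tip <- config_roi(config$calibration$tip_roi, "gray_tip")
  cheek <- config_roi(config$rois$cheek, "cheek")
  e2c <- config_roi(config$rois$eye_to_cheek, "eye_to_cheek")
  pp <- config_pore_params(config)

  rows <- list()
  qc <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(sidecar))) {
    sc <- sidecar[i, ]
    meta <- tryCatch(
      capture_metadata(sc$subject_id, sc$study_day, sc$timepoint,
                       sc$face_side),
      error = function(e) stop("malformed sidecar row ", i, " (",
                               sc$file, "): ", conditionMessage(e)))
    path <- file.path(image_dir, sc$file)
    if (!file.exists(path)) {
      skipped <- c(skipped, sc$file)
      next
    }
    img <- read_image(path, meta = meta)
    ref <- withCallingHandlers(
      measure_gray(img, tip, config$calibration$nominal_reflectance),
      warning = function(w) invokeRestart("muffleWarning"))
    cal <- calibrate(img, ref)
    pores <- pore_area(cal, cheek, pp)
    rough <- roughness_score(cal, e2c, band = config$roughness$band,
                             sigma_illum = config$roughness$sigma_illum)
    red <- redness_score(cal, cheek, band = config$redness$band,
                         w_brightness = config$redness$w_brightness,
                         w_variation = config$redness$w_variation)
    vals <- c(pore_area = pores$total_area_au,
              roughness = rough$roughness_au,
              redness = red$redness_au)
    for (m in names(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = meta$subject_id, study_day = meta$study_day,
        week_index = meta$week_index, timepoint = meta$timepoint,
        face_side = meta$face_side, metric = m, value_au = vals[[m]])
    }
    qc[[length(qc) + 1L]] <- data.frame(
      file = sc$file, n_clipped = cal$n_clipped,
      tip_flagged = ref$flagged, n_pores = length(pores$candidates))
  }
  if (!length(rows))
    stop("no sidecar row resolved to a readable image")
  records <- average_sides(metric_records(do.call(rbind, rows)))
  qc <- do.call(rbind, qc)
  write_records(records, file.path(out_dir, "metrics.csv"))
  utils::write.csv(qc, file.path(out_dir, "qc_log.csv"), row.names = FALSE)
  write_resolved_config(config, out_dir)
  if (length(skipped))
    message("skipped ", length(skipped), " missing image(s): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  list(records = records, qc = qc, skipped = skipped,
       status = if (length(skipped)) 2L else 0L)
}

#' Fluctuation report for one metric
#'
#' Writes the weekly-average table, the comparison table (baseline timepoint
#' contrasts and treatment effects) and a weekly fluctuation line plot
#' (three lines, one per daily timepoint, over the eight study weeks).
#'
#' @param records metric-record data frame or CSV path.
#' @param metric metric name.
#' @param out_dir output directory.
#' @param config configuration list (uses the `fluctuation` section).
#' @return list with `weekly`, `comparisons` and output `files`, invisibly.
#' @export
fluctuation_report <- function(records, metric, out_dir,
                               config = default_config()) {
  if (is.character(records)) records <- read_records(records)
  metric <- match.arg(metric, METRICS)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weekly <- weekly_average(records, metric)
  # small cohorts cannot support the tests (insufficient-data errors); the
  # report then still delivers the weekly table and plot
  base_cmp <- tryCatch(
    compare_timepoints_baseline(records, metric,
                                adjust = isTRUE(config$fluctuation$adjust)),
    error = function(e) { message("baseline comparison skipped: ",
                                  conditionMessage(e)); NULL })
  treat_cmp <- tryCatch(
    treatment_effect(records, metric, baseline = config$fluctuation$baseline),
    error = function(e) { message("treatment comparison skipped: ",
                                  conditionMessage(e)); NULL })
  cmp_rows <- lapply(c(base_cmp, treat_cmp), function(r) {
    data.frame(contrast = r$label, method = r$method, statistic = r$statistic,
               p_value = r$p_value, adjusted = r$adjusted,
               significant = r$significant)
  })
  comparisons <- do.call(rbind, cmp_rows)
  if (is.null(comparisons))
    comparisons <- data.frame(contrast = character(0), method = character(0),
                              statistic = numeric(0), p_value = numeric(0),
                              adjusted = logical(0), significant = logical(0))
  rownames(comparisons) <- NULL

  weekly_file <- file.path(out_dir, paste0("weekly_", metric, ".csv"))
  cmp_file <- file.path(out_dir, paste0("comparisons_", metric, ".csv"))
  plot_file <- file.path(out_dir, paste0("weekly_", metric, ".png"))
  utils::write.csv(weekly, weekly_file, row.names = FALSE)
  utils::write.csv(comparisons, cmp_file, row.names = FALSE)
  plot_weekly(weekly, metric, plot_file)
  invisible(list(weekly = weekly, comparisons = comparisons,
                 files = c(weekly_file, cmp_file, plot_file)))
}

# weekly fluctuation line plot, one line per daily timepoint
plot_weekly <- function(weekly, metric, path) {
  grDevices::png(path, width = 900, height = 520)
  on.exit(grDevices::dev.off())
  weeks <- sort(unique(weekly$week_index))
  cols <- c(morning_wake = "#D55E00", morning_wash = "#0072B2",
            evening_wash = "#009E73")
  ylim <- range(weekly$mean_au, na.rm = TRUE)
  graphics::plot(NULL, xlim = range(weeks), ylim = ylim,
                 xlab = "study week (baseline < 0, treatment > 0)",
                 ylab = paste(metric, "(au)"),
                 main = paste("Weekly average", metric, "by daily timepoint"))
  graphics::abline(v = 0, lty = 3, col = "gray60")
  for (tp in TIMEPOINTS) {
    d <- weekly[weekly$timepoint == tp, ]
    d <- d[order(d$week_index), ]
    graphics::lines(d$week_index, d$mean_au, type = "b", pch = 16,
                    col = cols[[tp]])
  }
  graphics::legend("topright", legend = TIMEPOINTS, col = cols[TIMEPOINTS],
                   lty = 1, pch = 16, bty = "n")
}
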