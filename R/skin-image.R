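TIMEPOINTS <- c("morning_wake", "morning_wash", "evening_wash")
FACE_SIDES <- c("left", "right")
ROI_LABELS <- c("cheek", "eye_to_cheek", "gray_tip")

#' Capture session metadata
#'
#' One record per captured half-face image: who, when in the study, which of
#' the three daily sessions, and which half of the face. Study days 1--28 are
#' the baseline period (weeks -4..-1, no product); days 29--56 are the
#' treatment period (weeks 1..4). Week 0 does not exist.
#'
#' @param subject_id opaque subject identifier (character scalar).
#' @param study_day integer in 1..56.
#' @param timepoint one of `"morning_wake"` (morning after wake-up),
#'   `"morning_wash"` (morning after face wash), `"evening_wash"` (evening
#'   after face wash).
#' @param face_side `"left"` or `"right"`, or `NA` once sides have been
#'   averaged.
#' @param week_index optional; if supplied it must agree with `study_day`.
#' @return an object of class `capture_metadata`.
#' @export
capture_metadata <- function(subject_id, study_day, timepoint,
                             face_side = NA_character_, week_index = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  study_day <- as.integer(study_day)
  if (is.na(study_day) || study_day < 1L || study_day > 56L)
    stop("study_day must be an integer in 1..56, got ", study_day)
  wk <- week_from_day(study_day)
  if (!is.null(week_index) && as.integer(week_index) != wk)
    stop("week_index ", week_index, " inconsistent with study_day ",
         study_day, " (expected ", wk, ")")
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  if (!is.na(face_side)) face_side <- match.arg(face_side, FACE_SIDES)
  structure(list(subject_id = subject_id, study_day = study_day,
                 week_index = wk, timepoint = timepoint,
                 face_side = face_side),
            class = "capture_metadata")
}

#' Map a study day to its week index
#'
#' Days 1--28 map to weeks -4..-1, days 29--56 to weeks 1..4; there is no
#' week 0.
#'
#' @param study_day integer vector in 1..56.
#' @return integer vector of week indices.
#' @export
week_from_day <- function(study_day) {
  study_day <- as.integer(study_day)
  if (any(is.na(study_day) | study_day < 1L | study_day > 56L))
    stop("study_day out of range 1..56")
  ifelse(study_day <= 28L,
         -4L + (study_day - 1L) %/% 7L,
         1L + (study_day - 29L) %/% 7L)
}

#' Rectangular region of interest
#'
#' Pixel bounds are row-major, 0-based and half-open `[start, stop)`, so a
#' full-frame ROI on an H x W image is `roi(0, H, 0, W)`. Labels identify the
#' measurement region: `cheek` (pores, redness), `eye_to_cheek` (roughness)
#' or `gray_tip` (calibration reference patch).
#'
#' @param row_start,row_stop,col_start,col_stop 0-based half-open bounds.
#' @param label one of `"cheek"`, `"eye_to_cheek"`, `"gray_tip"`.
#' @return an object of class `roi`.
#' @export
roi <- function(row_start, row_stop, col_start, col_stop, label = "cheek") {
  b <- as.integer(c(row_start, row_stop, col_start, col_stop))
  if (any(is.na(b)) || any(b < 0L))
    stop("ROI bounds must be nonnegative integers")
  if (b[2] <= b[1] || b[4] <= b[3])
    stop("ROI must have positive extent (half-open [start, stop))")
  label <- match.arg(label, ROI_LABELS)
  structure(list(row_start = b[1], row_stop = b[2],
                 col_start = b[3], col_stop = b[4], label = label),
            class = "roi")
}

roi_height <- function(r) r$row_stop - r$row_start
roi_width  <- function(r) r$col_stop - r$col_start
roi_area   <- function(r) roi_height(r) * roi_width(r)

check_roi_bounds <- function(r, dim_hw) {
  if (r$row_stop > dim_hw[1])
    stop("ROI row_stop ", r$row_stop, " exceeds image height ", dim_hw[1])
  if (r$col_stop > dim_hw[2])
    stop("ROI col_stop ", r$col_stop, " exceeds image width ", dim_hw[2])
  invisible(r)
}

# measurement ROIs must give a statistically meaningful pixel count
check_roi_measurement_area <- function(r) {
  if (roi_area(r) < 32L * 32L)
    stop("measurement ROI area ", roi_area(r), " px is below the 32x32 floor")
  invisible(r)
}

#' Construct a skin image
#'
#' The unit of all image analysis: an H x W x 3 raster of intensities in
#' `[0, 1]` plus capture metadata and a calibration state. `color_state`
#' starts at `"raw"` and may only move to `"calibrated"` (see
#' [calibrate()]).
#'
#' @param pixels numeric H x W x 3 array, values in `[0, 1]`.
#' @param meta a [capture_metadata()] object (or `NULL` for anonymous
#'   fixtures).
#' @param bit_depth_origin 8 or 16, the bit depth the raster came from.
#' @param color_state `"raw"` or `"calibrated"`.
#' @return an object of class `skin_image`.
#' @export
skin_image <- function(pixels, meta = NULL, bit_depth_origin = 8L,
                       color_state = c("raw", "calibrated")) {
  color_state <- match.arg(color_state)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("pixels must be an H x W x 3 array, got dims ",
         paste(d, collapse = "x"))
  if (d[1] < 64L || d[2] < 64L)
    stop("image must be at least 64x64 px, got ", d[1], "x", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  if (!bit_depth_origin %in% c(8L, 16L))
    stop("bit_depth_origin must be 8 or 16")
  structure(list(pixels = pixels, bit_depth_origin = as.integer(bit_depth_origin),
                 color_state = color_state, meta = meta,
                 gains = NULL, n_clipped = NULL),
            class = "skin_image")
}

#' @export
print.skin_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<skin_image %dx%d, %d-bit origin, %s>\n",
              d[1], d[2], x$bit_depth_origin, x$color_state))
  if (!is.null(x$meta))
    cat(sprintf("  subject %s day %d (%s, %s)\n", x$meta$subject_id,
                x$meta$study_day, x$meta$timepoint, x$meta$face_side))
  invisible(x)
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi %s [%d,%d)x[%d,%d)>\n", x$label,
              x$row_start, x$row_stop, x$col_start, x$col_stop))
  invisible(x)
}

#' Extract a rectangular subimage
#'
#' Returns a new [skin_image()] holding the pixels of `roi`; metadata and
#' color state are preserved. Extraction is idempotent: re-extracting the
#' full ROI of an extraction is the identity.
#'
#' @param img a [skin_image()].
#' @param roi an [roi()] within the image bounds.
#' @return a `skin_image` of shape (row_stop-row_start, col_stop-col_start, 3).
#' @export
extract_roi <- function(img, roi) {
  stopifnot(inherits(img, "skin_image"), inherits(roi, "roi"))
  check_roi_bounds(roi, dim(img$pixels))
  px <- img$pixels[(roi$row_start + 1L):roi$row_stop,
                   (roi$col_start + 1L):roi$col_stop, , drop = FALSE]
  out <- img
  out$pixels <- px
  out
}

# same as extract_roi but returns the raw array and skips the 64x64 floor
roi_pixels <- function(img, roi) {
  check_roi_bounds(roi, dim(img$pixels))
  img$pixels[(roi$row_start + 1L):roi$row_stop,
             (roi$col_start + 1L):roi$col_stop, , drop = FALSE]
}

#' Rec. 709 luminance of an RGB raster
#'
#' `0.2126 R + 0.7152 G + 0.0722 B`, computed on the pixel array of a
#' [skin_image()] or on a bare H x W x 3 array.
#'
#' @param x a `skin_image` or an H x W x 3 array.
#' @return an H x W numeric matrix.
#' @export
luminance <- function(x) {
  px <- if (inherits(x, "skin_image")) x$pixels else x
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
}
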