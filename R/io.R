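#' Read an RGB image file
#'
#' Decodes a 3-channel image and rescales intensities to `[0, 1]` by dividing
#' by `2^bit_depth - 1`. Supported containers: PNM (PPM `P3`/`P6`, 8- or
#' 16-bit, read natively) always; PNG and JPEG when the `png`/`jpeg` packages
#' are installed. The result starts life uncalibrated (`color_state = "raw"`).
#'
#' @param path path to a decodable image file.
#' @param meta optional [capture_metadata()] attached to the result.
#' @return a [skin_image()].
#' @export
read_image <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  magic <- readBin(path, "raw", n = 8L)
  if (length(magic) >= 2L && magic[1] == as.raw(0x50) &&
      magic[2] %in% as.raw(c(0x32, 0x33, 0x35, 0x36))) {       # "P2".."P6"
    dec <- read_pnm(path)
  } else if (length(magic) >= 4L &&
             identical(magic[1:4], as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG support requires the 'png' package")
    px <- png::readPNG(path)
    dec <- list(pixels = px, bit_depth = 8L)                   # readPNG pre-scales
  } else if (length(magic) >= 2L &&
             identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("JPEG support requires the 'jpeg' package")
    dec <- list(pixels = jpeg::readJPEG(path), bit_depth = 8L)
  } else {
    stop("unrecognized image format (expected PNM, PNG or JPEG): ", path)
  }
  px <- dec$pixels
  if (length(dim(px)) == 2L || dim(px)[3] == 1L)
    stop("expected a 3-channel image, got 1 channel: ", path)
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]        # drop alpha
  if (dim(px)[3] != 3L)
    stop("expected a 3-channel image, got ", dim(px)[3], " channels: ", path)
  skin_image(px, meta = meta, bit_depth_origin = dec$bit_depth,
             color_state = "raw")
}

# PNM decoder: P2/P5 (gray) and P3/P6 (RGB), maxval 255 or 65535.
# Values are returned already divided by maxval; gray images come back as a
# single-channel array so read_image can reject them with a clear message.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pnm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PNM header in ", path)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P2", "P3")) {
    vals <- numeric(n); got <- 0L
    while (got < n) {
      v <- tok()
      if (is.null(v)) stop("truncated ASCII PNM data in ", path)
      got <- got + 1L
      vals[got] <- as.numeric(v)
    }
  } else {
    if (maxval <= 255L) {
      vals <- as.numeric(readBin(con, "integer", n = n, size = 1L,
                                 signed = FALSE))
    } else {
      # 16-bit raw PNM is big-endian
      vals <- as.numeric(readBin(con, "integer", n = n, size = 2L,
                                 signed = FALSE, endian = "big"))
    }
    if (length(vals) < n) stop("truncated raw PNM data in ", path)
  }
  # PNM stores row-major, channel-interleaved
  px <- aperm(array(vals / maxval, dim = c(nch, w, h)), c(3, 2, 1))
  list(pixels = px, bit_depth = if (maxval <= 255L) 8L else 16L)
}

# whitespace/comment-aware token reader for PNM headers and ASCII payloads
pnm_tokenizer <- function(con) {
  function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "")
        return(if (length(tok)) paste(tok, collapse = "") else NULL)
      if (ch == "#") {                        # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) return(paste(tok, collapse = ""))
        next
      }
      tok <- c(tok, ch)
    }
  }
}

#' Write an RGB image file
#'
#' Writes PNM (PPM, raw `P6`) natively at 8 or 16 bit, or PNG when the `png`
#' package is available (chosen by file extension `.ppm`/`.pnm` vs `.png`).
#' Pixels are quantized to `2^bit_depth - 1` levels.
#'
#' @param img a [skin_image()] or an H x W x 3 array in `[0, 1]`.
#' @param path output path; extension selects the container.
#' @param bit_depth 8 or 16 (16-bit PNM only; PNG is written 8-bit unless
#'   the array is passed straight through by `png::writePNG`).
#' @export
write_image <- function(img, path, bit_depth = NULL) {
  px <- if (inherits(img, "skin_image")) img$pixels else img
  if (is.null(bit_depth))
    bit_depth <- if (inherits(img, "skin_image")) img$bit_depth_origin else 8L
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ppm", "pnm")) {
    write_ppm(px, path, bit_depth)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG support requires the 'png' package")
    png::writePNG(px, path)
  } else {
    stop("unsupported output extension '.", ext, "' (use .ppm or .png)")
  }
  invisible(path)
}

write_ppm <- function(px, path, bit_depth = 8L) {
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L,
            bit_depth %in% c(8L, 16L))
  maxval <- 2L^as.integer(bit_depth) - 1L
  d <- dim(px)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n%d\n", d[2], d[1], maxval), con,
            eos = NULL)
  q <- array(as.integer(round(pmin(pmax(px, 0), 1) * maxval)), dim = d)
  q <- as.vector(aperm(q, c(3, 2, 1)))            # interleave channels, row-major
  if (maxval <= 255L) {
    writeBin(as.raw(q), con)
  } else {
    writeBin(as.raw(as.vector(rbind(q %/% 256L, q %% 256L))), con)
  }
  invisible(path)
}

RECORD_COLUMNS <- c("subject_id", "study_day", "week_index", "timepoint",
                    "face_side", "metric", "value_au")
METRICS <- c("pore_area", "roughness", "redness")

#' Write metric records to CSV
#'
#' One row per (subject, day, timepoint, face side, metric) observation with
#' the columns `subject_id, study_day, week_index, timepoint, face_side,
#' metric, value_au`. Round-trips losslessly with [read_records()].
#'
#' @param records a metric-record data frame (see [metric_records()]).
#' @param path output CSV path.
#' @export
write_records <- function(records, path) {
  records <- metric_records(records)
  if (nrow(records) == 0L) stop("records must be nonempty")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read metric records from CSV
#'
#' @param path CSV written by [write_records()] (or following its layout).
#' @return a validated metric-record data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("cannot read records file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  metric_records(df)
}

#' Validate a metric-record table
#'
#' Checks column layout, enum levels, day/week consistency and finiteness of
#' `value_au`, and returns the table with canonical column order and types.
#' `face_side` may be `NA` for side-averaged records.
#'
#' @param df a data frame with the columns of [write_records()].
#' @return the validated data frame.
#' @export
metric_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing))
    stop("records table lacks columns: ", paste(missing, collapse = ", "))
  df <- df[RECORD_COLUMNS]
  df$subject_id <- as.character(df$subject_id)
  df$study_day <- as.integer(df$study_day)
  df$week_index <- as.integer(df$week_index)
  df$value_au <- as.numeric(df$value_au)
  if (nrow(df)) {
    if (any(df$week_index != week_from_day(df$study_day)))
      stop("week_index inconsistent with study_day in records table")
    if (!all(df$timepoint %in% TIMEPOINTS))
      stop("unknown timepoint labels in records table")
    if (!all(is.na(df$face_side) | df$face_side %in% FACE_SIDES))
      stop("unknown face_side labels in records table")
    if (!all(df$metric %in% METRICS))
      stop("unknown metric labels in records table")
    if (!all(is.finite(df$value_au)))
      stop("value_au must be finite")
  }
  rownames(df) <- NULL
  df
}

#' Average left/right half-face values into one record per session
#'
#' The capture protocol takes one image per half-face; downstream analytics
#' use one value per session, the mean of the available sides.
#'
#' @param records a metric-record data frame.
#' @return records with `face_side = NA` and one row per
#'   (subject, day, timepoint, metric).
#' @export
average_sides <- function(records) {
  records <- metric_records(records)
  agg <- stats::aggregate(
    value_au ~ subject_id + study_day + week_index + timepoint + metric,
    data = records, FUN = mean)
  agg$face_side <- NA_character_
  out <- metric_records(agg[c("subject_id", "study_day", "week_index",
                              "timepoint", "face_side", "metric", "value_au")])
  out[order(out$subject_id, out$study_day, match(out$timepoint, TIMEPOINTS),
            out$metric), , drop = FALSE]
}
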