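# Gray-reference color calibration. The capture attachment carries neutral
# gray tips at a fixed frame position; measuring their apparent RGB and
# rescaling each channel to the tip's known reflectance (a von-Kries-style
# per-channel gain, no offset, no cross-channel matrix) removes the global
# color cast of the LED/exposure combination post hoc.

#' Construct a gray reference
#'
#' @param measured_rgb length-3 positive numeric, the per-channel mean of the
#'   gray-tip ROI.
#' @param nominal_reflectance the tip's known gray level in (0, 1); default
#'   mid-gray 0.5.
#' @param flagged logical, `TRUE` when the tip patch looked non-uniform
#'   (possible occlusion); carried as a warning-level QC flag.
#' @return an object of class `gray_reference`.
#' @export
gray_reference <- function(measured_rgb, nominal_reflectance = 0.5,
                           flagged = FALSE) {
  measured_rgb <- as.numeric(measured_rgb)
  stopifnot(length(measured_rgb) == 3L)
  if (anyNA(measured_rgb) || any(measured_rgb <= 0))
    stop("calibration undefined: gray-tip channel mean is zero or negative ",
         "(black or missing frame?)")
  if (nominal_reflectance <= 0 || nominal_reflectance >= 1)
    stop("nominal_reflectance must lie in (0, 1)")
  structure(list(measured_rgb = measured_rgb,
                 nominal_reflectance = nominal_reflectance,
                 flagged = isTRUE(flagged)),
            class = "gray_reference")
}

#' Measure the gray calibration tip
#'
#' Averages each channel over the gray-tip ROI. A flat neutral patch should
#' have a small per-channel coefficient of variation; a CV of 0.2 or more
#' suggests the tip was occluded or misplaced and flags the reference (the
#' measurement is still returned).
#'
#' @param img a raw [skin_image()].
#' @param tip_roi an [roi()] with label `gray_tip`, at least 32x32 px.
#' @param nominal_reflectance the tip's known gray level; default 0.5.
#' @return a [gray_reference()].
#' @export
measure_gray <- function(img, tip_roi, nominal_reflectance = 0.5) {
  stopifnot(inherits(img, "skin_image"), inherits(tip_roi, "roi"))
  if (tip_roi$label != "gray_tip")
    stop("tip_roi must carry label 'gray_tip', got '", tip_roi$label, "'")
  check_roi_measurement_area(tip_roi)
  px <- roi_pixels(img, tip_roi)
  mu <- apply(px, 3, mean)
  if (any(mu == 0))
    stop("calibration undefined: gray-tip channel mean is zero (black frame)")
  cv <- apply(px, 3, stats::sd) / mu
  flagged <- any(cv >= 0.2)
  if (flagged)
    warning("gray tip non-uniform (per-channel CV ",
            paste(sprintf("%.3f", cv), collapse = ", "),
            "); occluded tip suspected")
  gray_reference(mu, nominal_reflectance, flagged = flagged)
}

#' Calibrate an image against its gray reference
#'
#' Multiplies channel c by `gain_c = nominal_reflectance / measured_rgb[c]`
#' and clips to `[0, 1]`. After calibration the gray tip averages to the
#' nominal reflectance in every channel, so any per-channel exposure or
#' illuminant gain present at capture cancels exactly. Clipped pixels are
#' counted (`$n_clipped`) rather than silently saturated, and the gains used
#' are recorded (`$gains`).
#'
#' @param img a [skin_image()] with `color_state = "raw"`.
#' @param ref a [gray_reference()].
#' @return the calibrated [skin_image()].
#' @export
calibrate <- function(img, ref) {
  stopifnot(inherits(img, "skin_image"), inherits(ref, "gray_reference"))
  if (img$color_state != "raw")
    stop("image is already calibrated; color_state transitions only raw -> calibrated")
  gains <- ref$nominal_reflectance / ref$measured_rgb
  px <- sweep(img$pixels, 3, gains, `*`)
  n_clipped <- sum(px > 1)
  px[px > 1] <- 1
  out <- img
  out$pixels <- px
  out$color_state <- "calibrated"
  out$gains <- gains
  out$n_clipped <- n_clipped
  out
}
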