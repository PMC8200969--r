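# Cheek redness from a hemoglobin tone index. Hemoglobin absorbs green light
# preferentially, so the erythema-style optical-density contrast
# h = log10(R/G) rises where blood content is high. The score combines the
# mean level (brightness) with the band-limited spatial variation of the
# index (red blotches vary over mm-cm scales, an order of magnitude below
# the roughness texture band).

#' Hemoglobin tone map
#'
#' Per-pixel `h = log10(R / G)` with channels floored at `1e-4`; 0 on neutral
#' gray, positive for red-shifted skin.
#'
#' @param img a calibrated [skin_image()].
#' @param roi an [roi()] with label `cheek`.
#' @return matrix of hemoglobin index values.
#' @export
hemoglobin_map <- function(img, roi) {
  stopifnot(inherits(img, "skin_image"), inherits(roi, "roi"))
  if (roi$label != "cheek")
    stop("hemoglobin_map expects a ROI labeled 'cheek', got '", roi$label, "'")
  px <- roi_pixels(img, roi)
  R <- pmax(px[, , 1], 1e-4)
  G <- pmax(px[, , 2], 1e-4)
  log10(R / G)
}

#' Fourier-filtered redness score
#'
#' Decomposes the hemoglobin map into a brightness component
#' (`100 * mean(h)`) and a variation component (`100 * RMS` of the Fourier
#' annulus band-pass of `h`, same Hann-tapered machinery as the roughness
#' score), and reports their weighted sum. With unit weights,
#' `redness_au = brightness_component_au + variation_component_au`.
#'
#' @param img a calibrated [skin_image()].
#' @param roi an [roi()] with label `cheek`.
#' @param band blotch band `(low, high)` cycles/px; default `c(0.005, 0.05)`.
#' @param w_brightness,w_variation component weights (default 1 each; the
#'   original instrument's weighting is unknown).
#' @return an object of class `redness_result` with fields `redness_au`,
#'   `brightness_component_au`, `variation_component_au`,
#'   `band_cycles_per_px`.
#' @export
redness_score <- function(img, roi, band = c(0.005, 0.05),
                          w_brightness = 1, w_variation = 1) {
  stopifnot(inherits(img, "skin_image"))
  if (img$color_state != "calibrated")
    stop("redness_score requires a calibrated image")
  check_roi_measurement_area(roi)
  check_band(band)
  h <- hemoglobin_map(img, roi)
  brightness <- w_brightness * 100 * mean(h)
  variation <- w_variation * 100 * band_rms(h, band)
  structure(list(redness_au = brightness + variation,
                 brightness_component_au = brightness,
                 variation_component_au = variation,
                 band_cycles_per_px = band),
            class = "redness_result")
}

#' @export
print.redness_result <- function(x, ...) {
  cat(sprintf(
    "<redness_result: %.3f au (brightness %.3f + variation %.3f)>\n",
    x$redness_au, x$brightness_component_au, x$variation_component_au))
  invisible(x)
}
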