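# Surface roughness from relative shadows: fine skin topography casts small
# local shadows under the attachment's oblique LED light. Dividing luminance
# by a heavily smoothed copy of itself removes slow illumination and face
# shape shading and leaves the relative local shading field, whose
# spatial-frequency content in a fixed band is summarized as an RMS score.

#' Relative shadow map
#'
#' `s = lum / G(sigma_illum)*lum - 1`: the luminance divided by its local
#' (large-scale) mean, minus one. Slow illumination gradients cancel in the
#' ratio, so the map is invariant to global brightness gain and approximately
#' zero-mean on large rasters; what remains is the relative shading of fine
#' surface topography.
#'
#' @param lum 2-D luminance matrix; floored at `1e-4` before division.
#' @param sigma_illum scale of the illumination estimate, px (default 30).
#' @return matrix of relative shading values.
#' @export
relative_shadow_map <- function(lum, sigma_illum = 30) {
  stopifnot(is.matrix(lum))
  lum <- pmax(lum, 1e-4)
  lum / gaussian_blur(lum, sigma_illum) - 1
}

#' Shadow-spectrum roughness score
#'
#' Band-passes the relative shadow map of the ROI with a radial ideal annulus
#' `[low, high)` cycles/px in the 2-D Fourier domain (Hann-tapered against
#' border leakage) and reports `roughness_au = 100 * RMS` of the in-band
#' component. A spatially constant ROI scores 0.
#'
#' @param img a calibrated [skin_image()].
#' @param roi an [roi()] with label `eye_to_cheek`.
#' @param band `(low, high)` cycles/px; default `c(0.02, 0.15)`, roughly
#'   0.2--1.5 cycles/mm at the generator's 10 px/mm scale.
#' @param sigma_illum illumination-normalization scale, px.
#' @return an object of class `roughness_result` with fields `roughness_au`,
#'   `band_cycles_per_px`, `roi_area_px`.
#' @export
roughness_score <- function(img, roi, band = c(0.02, 0.15),
                            sigma_illum = 30) {
  stopifnot(inherits(img, "skin_image"), inherits(roi, "roi"))
  if (img$color_state != "calibrated")
    stop("roughness_score requires a calibrated image")
  if (roi$label != "eye_to_cheek")
    stop("roughness_score expects a ROI labeled 'eye_to_cheek', got '",
         roi$label, "'")
  check_roi_measurement_area(roi)
  check_band(band)
  lum <- luminance(roi_pixels(img, roi))
  s <- relative_shadow_map(lum, sigma_illum)
  structure(list(roughness_au = 100 * band_rms(s, band),
                 band_cycles_per_px = band,
                 roi_area_px = roi_area(roi)),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("<roughness_result: %.3f au in band [%.3f, %.3f) c/px>\n",
              x$roughness_au, x$band_cycles_per_px[1], x$band_cycles_per_px[2]))
  invisible(x)
}
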