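# Synthetic skin patches with exact ground truth. A patch is composed as
# base tone -> multiplicative illumination gradient -> exact-RMS in-band
# shading texture -> anti-aliased dark pore disks -> band-limited hemoglobin
# blotch field on the R/G ratio (plus optional mean red shift) -> gray tip
# -> per-channel capture gains -> quantization. Every stage is reproducible
# from the seed and its true parameters are returned for recovery tests.
#
# Scale convention: ~10 px/mm at the default 512x512 size, so default pore
# radii of 3-9 px correspond to visible facial pores of ~0.3-0.9 mm radius.

#' Synthetic patch parameters
#'
#' Defaults describe a plausible light-skin cheek patch at ~10 px/mm: mild
#' vignetting-style shading (10% peak), 3% RMS fine shading texture, 2% RMS
#' (in log10 R/G units) erythema blotches, and pores of 30% luminance drop.
#'
#' @param size `(H, W)` in px; `c(512, 512)` default, `c(1080, 1920)` is the
#'   capture-device preset.
#' @param base_rgb length-3 base skin tone in `[0, 1]`.
#' @param n_pores number of pore disks.
#' @param pore_radius_px `c(mean, sd)` of the (truncated) normal radius, px.
#' @param pore_contrast fractional luminance drop at the pore center.
#' @param texture_rms in-band RMS of the relative-shadow texture.
#' @param texture_rms_cheek optional override of the texture amplitude inside
#'   `pore_region` (the same underlying field, region-scaled); `NULL` keeps
#'   one global amplitude. Used by the cohort renderer to emulate
#'   region-specific roughness without coupling the pore detector's robust
#'   threshold to the roughness signal.
#' @param texture_band texture annulus, cycles/px.
#' @param blotch_rms in-band RMS of the hemoglobin blotch field (h units).
#' @param blotch_band blotch annulus, cycles/px.
#' @param h_shift constant hemoglobin index shift (h units; redness
#'   brightness control).
#' @param illum_gradient peak relative shading of the illumination gradient.
#' @param pore_region [roi()] restricting pore placement (the "cheek" of the
#'   patch), or `NULL` for the whole frame; pores keep a 5 px margin from the
#'   region border either way.
#' @param tip_roi [roi()] of the painted gray tip, or `NULL` for none.
#' @param tip_reflectance tip gray level.
#' @param gains per-channel capture gains; any value other than 1 leaves the
#'   patch in `raw` color state.
#' @param bit_depth 8 or 16, quantization depth; `NULL` skips quantization.
#' @param seed integer RNG seed.
#' @return an object of class `patch_params`.
#' @export
patch_params <- function(size = c(512L, 512L),
                         base_rgb = c(0.55, 0.44, 0.38),
                         n_pores = 25L,
                         pore_radius_px = c(5, 1),
                         pore_contrast = 0.3,
                         texture_rms = 0.03,
                         texture_rms_cheek = NULL,
                         texture_band = c(0.02, 0.15),
                         blotch_rms = 0.02,
                         blotch_band = c(0.005, 0.05),
                         h_shift = 0,
                         illum_gradient = 0.10,
                         pore_region = NULL,
                         tip_roi = NULL,
                         tip_reflectance = 0.5,
                         gains = c(1, 1, 1),
                         bit_depth = 16L,
                         seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 64L),
            length(base_rgb) == 3L, all(base_rgb > 0), all(base_rgb < 1),
            n_pores >= 0L, length(pore_radius_px) == 2L,
            pore_radius_px[1] > 0, pore_radius_px[2] >= 0,
            pore_contrast >= 0, pore_contrast < 1,
            texture_rms >= 0, blotch_rms >= 0,
            is.null(texture_rms_cheek) ||
              (texture_rms_cheek >= 0 && !is.null(pore_region)),
            illum_gradient >= 0, illum_gradient < 1,
            length(gains) == 3L, all(gains > 0))
  if (texture_rms > 0) check_band(texture_band)
  if (blotch_rms > 0) check_band(blotch_band)
  structure(list(size = as.integer(size), base_rgb = base_rgb,
                 n_pores = as.integer(n_pores),
                 pore_radius_px = pore_radius_px,
                 pore_contrast = pore_contrast,
                 texture_rms = texture_rms,
                 texture_rms_cheek = texture_rms_cheek,
                 texture_band = texture_band,
                 blotch_rms = blotch_rms, blotch_band = blotch_band,
                 h_shift = h_shift, illum_gradient = illum_gradient,
                 pore_region = pore_region,
                 tip_roi = tip_roi, tip_reflectance = tip_reflectance,
                 gains = gains, bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "patch_params")
}

# rejection-sample non-overlapping pore centers: >= 2 px gap between disks,
# >= 5 px (plus radius) from the placement-region border
place_pores <- function(h, w, n, radius_mean, radius_sd, region = NULL,
                        max_rounds = 1e4) {
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0), r = numeric(0)))
  if (is.null(region)) {
    b <- c(0, h, 0, w)
  } else {
    b <- c(region$row_start, region$row_stop, region$col_start,
           region$col_stop)
  }
  rows <- cols <- rad <- numeric(n)
  placed <- 0L
  rounds <- 0L
  while (placed < n) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("pore placement infeasible after ", max_rounds,
           " rejection rounds (density too high)")
    r <- max(1, stats::rnorm(1, radius_mean, radius_sd))
    margin <- r + 5
    if (b[2] - b[1] <= 2 * margin || b[4] - b[3] <= 2 * margin) next
    cy <- stats::runif(1, b[1] + margin, b[2] - margin)
    cx <- stats::runif(1, b[3] + margin, b[4] - margin)
    if (placed > 0L) {
      dmin <- sqrt((rows[1:placed] - cy)^2 + (cols[1:placed] - cx)^2)
      if (any(dmin < rad[1:placed] + r + 2)) next
    }
    placed <- placed + 1L
    rows[placed] <- cy; cols[placed] <- cx; rad[placed] <- r
  }
  data.frame(row = rows, col = cols, r = rad)
}

# anti-aliased union of disks: per-pixel coverage in [0, 1] with a 1-px ramp
pore_alpha <- function(h, w, pores) {
  A <- matrix(0, h, w)
  for (i in seq_len(nrow(pores))) {
    r <- pores$r[i]; cy <- pores$row[i]; cx <- pores$col[i]
    r1 <- max(1L, floor(cy - r - 2)); r2 <- min(h, ceiling(cy + r + 2))
    c1 <- max(1L, floor(cx - r - 2)); c2 <- min(w, ceiling(cx + r + 2))
    dy <- (r1:r2) - cy
    dx <- (c1:c2) - cx
    d <- sqrt(outer(dy^2, dx^2, `+`))
    a <- pmin(pmax(r + 0.5 - d, 0), 1)
    A[r1:r2, c1:c2] <- pmax(A[r1:r2, c1:c2], a)
  }
  A
}

#' Generate a synthetic skin patch with ground truth
#'
#' @param params a [patch_params()].
#' @return list with elements `image` (a [skin_image()]; `color_state` is
#'   `"calibrated"` when the applied gains are all 1, else `"raw"`) and
#'   `truth` (class `ground_truth`: `true_pore_area_fraction`, `pores`
#'   data frame, `true_texture_rms`, `true_blotch_rms`, `h_shift`, `gains`).
#' @export
generate_patch <- function(params = patch_params()) {
  stopifnot(inherits(params, "patch_params"))
  set.seed(params$seed)
  h <- params$size[1]; w <- params$size[2]

  # diagonal illumination gradient, peak relative shading at the far corner
  illum <- 1 - params$illum_gradient *
    (outer(0:(h - 1), 0:(w - 1), function(r, c) (r / (h - 1) + c / (w - 1)) / 2))

  tex_max <- max(params$texture_rms,
                 if (is.null(params$texture_rms_cheek)) 0
                 else params$texture_rms_cheek)
  if (tex_max > 0) {
    texture <- band_limited_field(h, w, params$texture_band, 1)
    amp <- matrix(params$texture_rms, h, w)
    if (!is.null(params$texture_rms_cheek)) {
      pr <- params$pore_region
      amp[(pr$row_start + 1L):pr$row_stop,
          (pr$col_start + 1L):pr$col_stop] <- params$texture_rms_cheek
    }
    texture <- texture * amp
  } else {
    texture <- matrix(0, h, w)
  }

  pores <- place_pores(h, w, params$n_pores,
                       params$pore_radius_px[1], params$pore_radius_px[2],
                       region = params$pore_region)
  alpha <- if (nrow(pores)) pore_alpha(h, w, pores) else matrix(0, h, w)

  blotch <- if (params$blotch_rms > 0)
    band_limited_field(h, w, params$blotch_band, params$blotch_rms)
  else matrix(0, h, w)
  hfield <- blotch + params$h_shift

  shade <- illum * (1 + texture) * (1 - params$pore_contrast * alpha)
  px <- array(0, dim = c(h, w, 3))
  px[, , 1] <- params$base_rgb[1] * shade * 10^(hfield / 2)
  px[, , 2] <- params$base_rgb[2] * shade * 10^(-hfield / 2)
  px[, , 3] <- params$base_rgb[3] * shade

  if (!is.null(params$tip_roi)) {
    tr <- params$tip_roi
    check_roi_bounds(tr, c(h, w))
    px[(tr$row_start + 1L):tr$row_stop,
       (tr$col_start + 1L):tr$col_stop, ] <- params$tip_reflectance
  }

  px <- sweep(px, 3, params$gains, `*`)
  px <- pmin(pmax(px, 0), 1)              # px first: pmax keeps dim attributes
  if (!is.null(params$bit_depth)) {
    maxval <- 2^as.integer(params$bit_depth) - 1
    px <- round(px * maxval) / maxval
  }

  state <- if (all(params$gains == 1)) "calibrated" else "raw"
  img <- skin_image(px,
                    bit_depth_origin = if (is.null(params$bit_depth)) 16L
                                       else as.integer(params$bit_depth),
                    color_state = state)
  truth <- structure(
    list(true_pore_area_fraction = sum(pi * pores$r^2) / (h * w),
         pores = pores,
         true_texture_rms = params$texture_rms,
         true_blotch_rms = params$blotch_rms,
         h_shift = params$h_shift,
         gains = params$gains),
    class = "ground_truth")
  list(image = img, truth = truth)
}
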