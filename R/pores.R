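# Pore quantification: follicular pores appear as small, dark, quasi-circular
# blobs. The pipeline is luminance -> difference-of-Gaussians edge/blob
# enhancement -> robust binarization -> 8-connected component screening by
# size, circularity and contrast -> total accepted area, normalized per ROI
# area and scaled x1000 into arbitrary units.

#' Pore detection parameters
#'
#' Defaults assume the generator's scale of roughly 10 px/mm, so the default
#' area gates correspond to pore diameters of about 0.3--5 mm.
#'
#' @param dog_sigma_small,dog_sigma_large difference-of-Gaussians scales, px;
#'   small < large.
#' @param binarize_k threshold offset in robust-SD units above the median
#'   response.
#' @param min_area,max_area accepted component area range, px.
#' @param circularity_min minimum `4*pi*A/P^2` (capped at 1) to accept.
#' @param min_contrast minimum luminance deficit (ROI mean minus blob mean).
#' @return an object of class `pore_params`.
#' @export
pore_params <- function(dog_sigma_small = 1.5, dog_sigma_large = 6,
                        binarize_k = 3.5, min_area = 9L, max_area = 2000L,
                        circularity_min = 0.6, min_contrast = 0.02) {
  stopifnot(dog_sigma_small > 0, dog_sigma_small < dog_sigma_large,
            circularity_min > 0, circularity_min <= 1,
            min_area >= 1L, min_area < max_area, min_contrast >= 0)
  structure(list(dog_sigma_small = dog_sigma_small,
                 dog_sigma_large = dog_sigma_large,
                 binarize_k = binarize_k,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area),
                 circularity_min = circularity_min,
                 min_contrast = min_contrast),
            class = "pore_params")
}

#' Difference-of-Gaussians blob enhancement
#'
#' `DoG = G(sigma_large) * lum - G(sigma_small) * lum`: the response is
#' positive where a pixel is darker than its surround (pore polarity), zero
#' on constant input, and invariant to adding a constant (the kernel is
#' DC-free).
#'
#' @param lum 2-D luminance matrix, values in `[0, 1]`.
#' @param sigma_small,sigma_large Gaussian scales in px.
#' @return matrix of band-pass responses.
#' @export
enhance_edges <- function(lum, sigma_small = 1.5, sigma_large = 6) {
  stopifnot(is.matrix(lum), sigma_small < sigma_large)
  if (min(dim(lum)) < 6 * sigma_large)
    stop("raster ", nrow(lum), "x", ncol(lum), " smaller than 6*sigma_large = ",
         6 * sigma_large, " per side")
  gaussian_blur(lum, sigma_large) - gaussian_blur(lum, sigma_small)
}

#' Robust binarization of a band-pass response
#'
#' `mask = resp > median(resp) + k * 1.4826 * MAD(resp)`; the robust scale
#' makes the threshold insensitive to the blobs themselves. A zero-variance
#' response yields an empty mask.
#'
#' @param resp response matrix from [enhance_edges()].
#' @param k threshold offset in robust-SD units.
#' @return logical matrix.
#' @export
binarize <- function(resp, k = 3) {
  stopifnot(is.matrix(resp))
  med <- stats::median(resp)
  s <- stats::mad(resp)                 # already includes the 1.4826 factor
  if (s == 0 && stats::var(as.vector(resp)) == 0)
    return(matrix(FALSE, nrow(resp), ncol(resp)))
  resp > med + k * s
}

# 8-connected component labeling by iterated minimum-label propagation with
# pointer-jumping path compression; labels are linear pixel indices.
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(list())
  big <- h * w + 1L
  L <- matrix(big, h, w)
  idx <- which(mask)
  L[idx] <- idx
  shifts <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  shift_min <- function(M, dr, dc) {
    S <- matrix(big, h, w)
    r1 <- max(1, 1 + dr):min(h, h + dr)
    c1 <- max(1, 1 + dc):min(w, w + dc)
    S[r1, c1] <- M[r1 - dr, c1 - dc, drop = FALSE]
    S
  }
  repeat {
    old <- L[idx]
    for (s in seq_len(nrow(shifts))) {
      L <- pmin(L, shift_min(L, shifts[s, 1], shifts[s, 2]))
    }
    L[-idx] <- big                       # non-mask pixels never carry labels
    # path compression: follow the label chain twice
    L[idx] <- L[L[idx]]
    L[idx] <- L[L[idx]]
    if (identical(L[idx], old)) break
  }
  split(idx, L[idx])
}

# Outer-boundary perimeter by Moore-neighbor contour tracing; steps count 1
# (edge moves) or sqrt(2) (diagonal moves). The trace is a deterministic walk
# over (pixel, backtrack-cell) states and terminates when the initial state
# recurs. Components of 1-2 px have degenerate contours; their perimeter
# would push 4*pi*A/P^2 above 1, which the caller caps.
trace_perimeter <- function(rows, cols) {
  n <- length(rows)
  if (n == 1L) return(0)
  rmin <- min(rows); cmin <- min(cols)
  # local grid padded by 1 so every neighbor lookup stays in bounds
  lr <- rows - rmin + 2L
  lc <- cols - cmin + 2L
  grid <- matrix(FALSE, max(lr) + 1L, max(lc) + 1L)
  grid[cbind(lr, lc)] <- TRUE
  # 8 neighbors clockwise starting north (rows grow downward)
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  # start: topmost, then leftmost pixel; its west neighbor is outside
  r0 <- min(lr); c0 <- min(lc[lr == r0])
  p <- c(r0, c0)
  b <- c(r0, c0 - 1L)
  init <- c(p, b)
  perim <- 0
  steps <- 0L
  max_steps <- 8L * n + 8L
  repeat {
    # direction from p to the backtrack cell
    dd <- b - p
    b_dir <- which(dr == dd[1] & dc == dd[2])
    q <- NULL
    prev <- b
    for (k in 1:8) {
      d <- ((b_dir + k - 1L) %% 8L) + 1L
      cand <- c(p[1] + dr[d], p[2] + dc[d])
      if (grid[cand[1], cand[2]]) {
        q <- cand
        break
      }
      prev <- cand
    }
    if (is.null(q)) return(0)             # isolated pixel (handled above)
    perim <- perim + if (all(abs(q - p) == 1L)) sqrt(2) else 1
    b <- prev
    p <- q
    if (identical(c(p, b), init)) return(perim)
    steps <- steps + 1L
    if (steps > max_steps) return(perim)  # safety net; unreachable on valid masks
  }
}

#' Detect pore candidates on a binary mask
#'
#' Labels 8-connected components of `mask` and keeps those with
#' `min_area <= area <= max_area`, circularity `4*pi*A/P^2 >= circularity_min`
#' (perimeter from Moore contour tracing, capped at 1), and mean luminance
#' deficit `>= min_contrast`. Components touching the ROI border are
#' discarded. Output is sorted by area descending, ties broken by centroid
#' (row, then col).
#'
#' @param mask logical matrix from [binarize()].
#' @param lum luminance matrix of the same shape.
#' @param params a [pore_params()].
#' @return list of `pore_candidate` objects (possibly empty).
#' @export
detect_pores <- function(mask, lum, params = pore_params()) {
  stopifnot(is.matrix(mask), is.matrix(lum),
            identical(dim(mask), dim(lum)))
  h <- nrow(mask); w <- ncol(mask)
  comps <- label_components(mask)
  roi_mean <- mean(lum)
  out <- list()
  for (px in comps) {
    area <- length(px)
    if (area < params$min_area || area > params$max_area) next
    rows <- ((px - 1L) %% h) + 1L
    cols <- ((px - 1L) %/% h) + 1L
    if (any(rows == 1L | rows == h | cols == 1L | cols == w)) next
    perim <- trace_perimeter(rows, cols)
    circ <- if (perim > 0) min(1, 4 * pi * area / perim^2) else 1
    if (circ < params$circularity_min) next
    contrast <- roi_mean - mean(lum[px])
    if (contrast < params$min_contrast) next
    out[[length(out) + 1L]] <- structure(
      list(centroid = c(row = mean(rows) - 1, col = mean(cols) - 1),
           area_px = area, perimeter_px = perim, circularity = circ,
           mean_contrast = contrast, pixels = px),
      class = "pore_candidate")
  }
  if (length(out) > 1L) {
    areas <- vapply(out, function(p) p$area_px, numeric(1))
    cr <- vapply(out, function(p) p$centroid[["row"]], numeric(1))
    cc <- vapply(out, function(p) p$centroid[["col"]], numeric(1))
    out <- out[order(-areas, cr, cc)]
  }
  out
}

#' Total pore area of a cheek ROI
#'
#' Runs the full pore pipeline — luminance, difference-of-Gaussians
#' enhancement, robust binarization, component screening — and reports
#' `total_area_au = 1000 * sum(accepted areas) / ROI area`, an ROI-size
#' independent arbitrary unit.
#'
#' @param img a calibrated [skin_image()].
#' @param roi an [roi()] with label `cheek`.
#' @param params a [pore_params()].
#' @return an object of class `pore_result` with fields `candidates`,
#'   `total_area_au`, `roi_area_px`, `params_used`.
#' @export
pore_area <- function(img, roi, params = pore_params()) {
  stopifnot(inherits(img, "skin_image"), inherits(roi, "roi"))
  if (img$color_state != "calibrated")
    stop("pore_area requires a calibrated image")
  if (roi$label != "cheek")
    stop("pore_area expects a ROI labeled 'cheek', got '", roi$label, "'")
  check_roi_measurement_area(roi)
  lum <- luminance(roi_pixels(img, roi))
  resp <- enhance_edges(lum, params$dog_sigma_small, params$dog_sigma_large)
  mask <- binarize(resp, params$binarize_k)
  cands <- detect_pores(mask, lum, params)
  total <- if (length(cands))
    sum(vapply(cands, function(p) p$area_px, numeric(1))) else 0
  structure(list(candidates = cands,
                 total_area_au = 1000 * total / roi_area(roi),
                 roi_area_px = roi_area(roi),
                 params_used = params),
            class = "pore_result")
}

#' @export
print.pore_result <- function(x, ...) {
  cat(sprintf("<pore_result: %d pores, total area %.3f au over %d px>\n",
              length(x$candidates), x$total_area_au, x$roi_area_px))
  invisible(x)
}
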