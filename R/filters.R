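# Spatial filtering primitives shared by the pore, roughness and redness
# pipelines: separable Gaussian smoothing with reflective boundaries, and
# radial (annulus) band selection in the 2-D Fourier domain with a Hann
# taper against border leakage.

# 1-D Gaussian smoothing operator as an n x n matrix with whole-sample
# reflective boundary handling; blur is then Br %*% X %*% t(Bc), which keeps
# everything in BLAS.
gaussian_operator <- function(n, sigma) {
  stopifnot(n >= 2L, sigma > 0)
  m <- max(1L, ceiling(3 * sigma))
  if (m > n - 1L)
    stop("raster extent ", n, " too small for sigma ", sigma,
         " (kernel radius ", m, ")")
  w <- stats::dnorm(-m:m, sd = sigma)
  w <- w / sum(w)
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in -m:m) {
    j <- i + k
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    ij <- cbind(i, j)
    B[ij] <- B[ij] + w[k + m + 1L]
  }
  B
}

#' Gaussian blur of a 2-D raster
#'
#' Separable Gaussian smoothing with reflective (mirror) boundary handling.
#' The kernel is truncated at 3 sigma and renormalized, so a constant raster
#' is reproduced exactly.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x))
  if (sigma <= 0) return(x)
  Br <- gaussian_operator(nrow(x), sigma)
  Bc <- gaussian_operator(ncol(x), sigma)
  Br %*% x %*% t(Bc)
}

# FFT sample frequencies in cycles/px (numpy fftfreq layout)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n) / n
}

# logical H x W mask selecting radial frequencies low <= f < high
annulus_mask <- function(h, w, band) {
  fr <- fft_freqs(h)
  fc <- fft_freqs(w)
  r <- sqrt(outer(fr^2, rep(1, w)) + outer(rep(1, h), fc^2))
  r >= band[1] & r < band[2]
}

check_band <- function(band) {
  if (length(band) != 2L || anyNA(band))
    stop("band must be two numbers (low, high) in cycles/px")
  if (band[1] <= 0 || band[2] > 0.5 || band[1] >= band[2])
    stop("band must satisfy 0 < low < high <= 0.5 cycles/px, got [",
         band[1], ", ", band[2], ")")
  band
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Band-limited RMS of a raster
#'
#' Measures the root-mean-square amplitude of the component of `x` inside a
#' radial spatial-frequency annulus `[low, high)` cycles/px. The raster is
#' mean-removed, tapered with a 2-D Hann window to suppress spectral leakage
#' from the borders, transformed, and the in-band power is read off by
#' Parseval's theorem and compensated for the window's power loss
#' (`mean(w^2)`), which is exact for stationary texture.
#'
#' @param x numeric matrix.
#' @param band numeric `(low, high)` in cycles/px, `0 < low < high <= 0.5`.
#' @return nonnegative scalar RMS in the units of `x`.
#' @export
band_rms <- function(x, band) {
  stopifnot(is.matrix(x))
  check_band(band)
  h <- nrow(x); w <- ncol(x)
  win <- outer(hann_window(h), hann_window(w))
  xw <- (x - mean(x)) * win
  F <- stats::fft(xw)
  m <- annulus_mask(h, w, band)
  band_power <- sum(Mod(F[m])^2) / (h * w)^2     # mean square of in-band part
  sqrt(band_power / mean(win^2))
}

# in-band component of the (windowed) raster, for QC visualisation
band_filter <- function(x, band) {
  stopifnot(is.matrix(x))
  check_band(band)
  h <- nrow(x); w <- ncol(x)
  win <- outer(hann_window(h), hann_window(w))
  F <- stats::fft((x - mean(x)) * win)
  F[!annulus_mask(h, w, band)] <- 0
  Re(stats::fft(F, inverse = TRUE)) / (h * w)
}

# zero-mean unit-variance noise filtered to an exact in-band field:
# all spectral energy inside the annulus, RMS exactly `rms`
band_limited_field <- function(h, w, band, rms) {
  check_band(band)
  if (rms == 0) return(matrix(0, h, w))
  z <- matrix(stats::rnorm(h * w), h, w)
  F <- stats::fft(z)
  F[!annulus_mask(h, w, band)] <- 0
  f <- Re(stats::fft(F, inverse = TRUE)) / (h * w)
  f <- f - mean(f)
  s <- sqrt(mean(f^2))
  if (s == 0) stop("band too narrow for raster size: no frequency samples")
  f * (rms / s)
}
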