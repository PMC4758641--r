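# Convolution kernels and fast convolution primitives.
#
# Spatial convolutions use zero padding and return the central ("same")
# portion; the orientation axis is circular. All Gaussian kernels are
# normalized to unit sum and truncated at radius ceil(3*sigma).

#' One-dimensional Gaussian kernel
#'
#' Unit-sum Gaussian kernel truncated at radius `ceiling(3 * sigma)`.
#'
#' @param sigma Positive SD in sample units.
#' @return Numeric vector of odd length.
#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Band matrix B such that B %*% X convolves the columns of X ("same" output,
# zero padding) with the kernel k.
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    M[i, j] <- k[j - i + r + 1L]
  }
  M
}

#' Gabor filter kernel
#'
#' A cosine-phase Gabor on an isotropic Gaussian envelope, truncated at
#' radius `ceiling(3 * sigma)`. The DC component is removed (projected out
#' along the envelope) so the filter does not respond to uniform luminance,
#' and the kernel is scaled so that its response to its own unrectified
#' template equals exactly 1 (matched-template normalization): drives are
#' therefore expressed in units of the optimal-stimulus response.
#'
#' Orientation convention: `theta` is the bar orientation measured from
#' vertical, so `theta = 0` prefers vertical bars (the carrier varies along
#' the x axis) and `theta = pi/2` prefers horizontal bars.
#'
#' @param sigma Envelope SD in pixels.
#' @param wavelength Carrier wavelength in pixels.
#' @param theta Preferred bar orientation in radians.
#' @return A square numeric matrix (rows = y, columns = x).
#' @keywords internal
gabor_kernel <- function(sigma, wavelength, theta) {
  stopifnot(sigma > 0, wavelength > 0)
  r <- ceiling(3 * sigma)
  x <- matrix(-r:r, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- matrix(-r:r, 2 * r + 1, 2 * r + 1)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  k <- env * cos(2 * pi * (x * cos(theta) + y * sin(theta)) / wavelength)
  k <- k - env * sum(k) / sum(env)
  k / sum(k^2)
}

#' Bank of oriented Gabor filters
#'
#' One kernel per orientation channel, at the channel orientations
#' `(k-1) * pi / n` for `k = 1..n` (8 channels: 0 to 157.5 degrees
#' inclusive, in steps of 22.5 degrees).
#'
#' @param params An [attnet_params()] object.
#' @return List of `n_orientations` square kernel matrices.
#' @export
gabor_filter_bank <- function(params) {
  lapply(orientations(params), function(th)
    gabor_kernel(params$sigma_bottom, params$stim_wavelength, th))
}

#' 2-D convolution, "same" output, zero padding
#'
#' FFT-based full convolution cropped to the input size, equivalent to a
#' direct double-loop sum with the image zero-padded.
#'
#' @param x Numeric matrix.
#' @param k Odd-sized numeric kernel matrix.
#' @return Matrix of the same size as `x`.
#' @keywords internal
conv2_same <- function(x, k) {
  n1 <- nrow(x); n2 <- ncol(x)
  k1 <- nrow(k); k2 <- ncol(k)
  p1 <- n1 + k1 - 1L; p2 <- n2 + k2 - 1L
  xp <- matrix(0, p1, p2); xp[1:n1, 1:n2] <- x
  kp <- matrix(0, p1, p2); kp[1:k1, 1:k2] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    (p1 * p2)
  r1 <- (k1 - 1L) %/% 2L; r2 <- (k2 - 1L) %/% 2L
  full[(r1 + 1L):(r1 + n1), (r2 + 1L):(r2 + n2)]
}

# Circulant matrix for the 1-D Gaussian convolution across the orientation
# axis (period n channels). sigma_ori is in radians; channel spacing is
# pi/n, so the SD in channel units is sigma_ori * n / pi. Weights whose
# truncated offsets alias onto the same channel are summed.
ori_circulant <- function(sigma_ori, n) {
  sig <- sigma_ori * n / pi
  r <- ceiling(3 * sig)
  off <- -r:r
  w <- exp(-off^2 / (2 * sig^2))
  w <- w / sum(w)
  M <- matrix(0, n, n)
  for (k in seq_len(n)) {
    j <- ((k - 1L + off) %% n) + 1L
    for (i in seq_along(off)) M[k, j[i]] <- M[k, j[i]] + w[i]
  }
  M
}
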