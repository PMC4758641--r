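# Stimulus generation: semi-rectified Gabor patches, multi-patch displays,
# and spectrally flat noise patches for spectral receptive-field estimation.
# All stimuli are non-negative luminance images ("full intensity" = 1.0).

#' Specification of a semi-rectified Gabor patch
#'
#' @param center Patch center `c(x, y)` in pixels (x = column, y = row);
#'   need not be integer.
#' @param orientation Bar orientation in radians; 0 is vertical.
#' @param amplitude Peak contrast; 1 is full intensity.
#' @param envelope_sd Gaussian envelope SD in pixels.
#' @param wavelength Carrier wavelength in pixels.
#' @param phase Carrier phase in radians; 0 puts a luminance peak at the
#'   center.
#' @return An object of class `gabor_spec`.
#' @export
gabor_spec <- function(center, orientation, amplitude = 1,
                       envelope_sd = 3, wavelength = 6, phase = 0) {
  if (!is.numeric(center) || length(center) != 2L)
    stop("center must be c(x, y)", call. = FALSE)
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("amplitude must be non-negative", call. = FALSE)
  if (envelope_sd <= 0) stop("envelope_sd must be positive", call. = FALSE)
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  structure(list(center = as.numeric(center),
                 orientation = as.numeric(orientation),
                 amplitude = as.numeric(amplitude),
                 envelope_sd = as.numeric(envelope_sd),
                 wavelength = as.numeric(wavelength),
                 phase = as.numeric(phase)),
            class = "gabor_spec")
}

#' Render a semi-rectified Gabor patch
#'
#' Evaluates the Gabor at every pixel and clips negative values to zero
#' (half-wave rectification), yielding a non-negative luminance image on a
#' zero background. With `phase = 0` the peak pixel value equals the
#' amplitude.
#'
#' @param spec A [gabor_spec()].
#' @param canvas Image size `c(width, height)` in pixels.
#' @return Numeric matrix (rows = y, columns = x) of non-negative values.
#' @export
gabor_patch <- function(spec, canvas) {
  stopifnot(inherits(spec, "gabor_spec"))
  w <- canvas[1]; h <- canvas[2]
  if (spec$center[1] < 1 || spec$center[1] > w ||
      spec$center[2] < 1 || spec$center[2] > h)
    stop("patch center lies outside the canvas", call. = FALSE)
  r <- 3 * spec$envelope_sd
  if (spec$center[1] - r < 1 || spec$center[1] + r > w ||
      spec$center[2] - r < 1 || spec$center[2] + r > h)
    warning("patch support (center +/- 3 envelope SD) is clipped by the canvas")
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - spec$center[1]
  y <- matrix(seq_len(h), h, w) - spec$center[2]
  env <- exp(-(x^2 + y^2) / (2 * spec$envelope_sd^2))
  carrier <- cos(2 * pi * (x * cos(spec$orientation) +
                           y * sin(spec$orientation)) /
                 spec$wavelength + spec$phase)
  pmax(spec$amplitude * env * carrier, 0)
}

#' Compose a multi-patch display
#'
#' Pixelwise sum of individually rendered patches; overlapping patches add
#' without clipping.
#'
#' @param specs Non-empty list of [gabor_spec()] objects.
#' @param canvas Image size `c(width, height)`.
#' @return Numeric matrix.
#' @export
compose_display <- function(specs, canvas) {
  if (!is.list(specs) || length(specs) == 0L)
    stop("specs must be a non-empty list of gabor_spec objects", call. = FALSE)
  Reduce(`+`, lapply(specs, gabor_patch, canvas = canvas))
}

# Default stimulus helper: a patch matched to the bottom-layer filter.
stimulus_patch <- function(params, center, orientation, amplitude = 1) {
  gabor_patch(gabor_spec(center, orientation, amplitude,
                         envelope_sd = params$stim_envelope_sd,
                         wavelength = params$stim_wavelength,
                         phase = params$stim_phase),
              params$canvas)
}

#' Spectrally flat noise patches
#'
#' Reproducible surrogate for whitened natural-image patches: Gaussian
#' white noise (flat expected power spectrum, as produced by whitening the
#' 1/f spectrum of natural images), half-wave rectified to a non-negative
#' luminance image and scaled to peak 1. Whitened images emulate the
#' output of retinal processing; the spectral-RF estimate relies on the
#' flat average spectrum and on the natural patch-to-patch spectral
#' fluctuations that reverse correlation exploits.
#'
#' @param n Number of patches (>= 1).
#' @param size Patch side length in pixels.
#' @param seed Integer seed; the same `(n, size, seed)` always returns
#'   identical patches. The caller's RNG state is left untouched.
#' @return List of `n` non-negative `size` x `size` matrices.
#' @export
whitened_noise_patches <- function(n, size, seed) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (size < 4) stop("size must be at least 4", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    w <- pmax(matrix(stats::rnorm(size * size), size, size), 0)
    if (max(w) > 0) w <- w / max(w)
    w
  })
}

#' Write / read an image as a CSV matrix
#'
#' Plain-text round trip preserving exact values, for regression tests and
#' interchange.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `read_image_csv` returns a numeric matrix.
#' @export
write_image_csv <- function(image, path) {
  utils::write.table(image, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write an image as an 8-bit PNG
#'
#' Values are scaled by `1 / max(image)` (or a supplied factor) into
#' `[0, 1]`; the scale factor is recorded in a JSON sidecar so the original
#' range can be recovered.
#'
#' @param image Numeric non-negative matrix.
#' @param path PNG file path; the sidecar is `paste0(path, ".json")`.
#' @param scale Optional divisor; defaults to `max(image)` (or 1 for an
#'   all-zero image).
#' @export
write_image_png <- function(image, path, scale = NULL) {
  if (is.null(scale)) scale <- if (max(image) > 0) max(image) else 1
  png::writePNG(pmin(image / scale, 1), path)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
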