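#' Model parameters
#'
#' Construct the full parameter set of the two-layer feedback attention
#' network. The defaults are the single global parameter set used for every
#' experiment; none of the experiment functions alter them.
#'
#' @param sigma_bottom SD (pixels) of the bottom-layer Gabor filter envelope;
#'   sets the effective size of V1-like receptive fields.
#' @param sigma_top SD (pixels) of the spatial Gaussian pooling from the
#'   bottom to the top layer; top-layer RFs are roughly four times the size
#'   of bottom-layer RFs.
#' @param sigma_inh SD (pixels) of the short-range divisive inhibition
#'   Gaussian, identical in both layers.
#' @param sigma_att_spat SD (pixels) of the spatial attention field.
#' @param sigma_ori SD (radians) of the Gaussian connection profile across
#'   preferred orientation, also the spread of feature-based attention.
#' @param alpha_spatial_att Peak amplitude of the spatial attention field.
#' @param alpha_feature_att Peak amplitude of the feature attention field.
#' @param alpha_fb Feedback strength multiplying the top-to-bottom
#'   modulatory field.
#' @param sigma_norm Calibration multiplier: each layer's normalization
#'   constant is set to `sigma_norm` times the layer's maximum pre-inhibition
#'   excitation during calibration.
#' @param c_bottom,c_top Divisive normalization constants. `NULL` means
#'   "not yet calibrated"; see [calibrate_constants()].
#' @param n_iterations Number of bottom-top-feedback passes run to
#'   equilibrate the network.
#' @param n_orientations Number of orientation channels per location.
#' @param canvas Image size as `c(width, height)` in pixels.
#' @param stim_envelope_sd,stim_wavelength,stim_phase Default Gabor stimulus
#'   parameters (pixels, pixels, radians); the stimulus is matched to the
#'   bottom-layer filter so that a full-intensity patch is the optimal input
#'   for one orientation channel.
#'
#' @return An object of class `attnet_params` (a validated list).
#' @examples
#' p <- attnet_params()
#' orientations(p)
#' @export
attnet_params <- function(sigma_bottom = 3,
                          sigma_top = 12,
                          sigma_inh = 1,
                          sigma_att_spat = 3,
                          sigma_ori = 1.1 * pi / 8,
                          alpha_spatial_att = 2,
                          alpha_feature_att = 0.2,
                          alpha_fb = 18,
                          sigma_norm = 0.6,
                          c_bottom = NULL,
                          c_top = NULL,
                          n_iterations = 30,
                          n_orientations = 8,
                          canvas = c(100, 100),
                          stim_envelope_sd = 3,
                          stim_wavelength = 6,
                          stim_phase = 0) {
  p <- list(sigma_bottom = sigma_bottom, sigma_top = sigma_top,
            sigma_inh = sigma_inh, sigma_att_spat = sigma_att_spat,
            sigma_ori = sigma_ori, alpha_spatial_att = alpha_spatial_att,
            alpha_feature_att = alpha_feature_att, alpha_fb = alpha_fb,
            sigma_norm = sigma_norm, c_bottom = c_bottom, c_top = c_top,
            n_iterations = n_iterations, n_orientations = n_orientations,
            canvas = as.integer(canvas),
            stim_envelope_sd = stim_envelope_sd,
            stim_wavelength = stim_wavelength, stim_phase = stim_phase)
  class(p) <- "attnet_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  sig <- c("sigma_bottom", "sigma_top", "sigma_inh", "sigma_att_spat",
           "sigma_ori", "sigma_norm", "stim_envelope_sd", "stim_wavelength")
  for (nm in sig)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  for (nm in c("alpha_spatial_att", "alpha_feature_att", "alpha_fb"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("parameter '", nm, "' must be a single non-negative number",
           call. = FALSE)
  for (nm in c("c_bottom", "c_top"))
    if (!is.null(p[[nm]]) && (!is.numeric(p[[nm]]) || p[[nm]] <= 0))
      stop("parameter '", nm, "' must be NULL or a positive number",
           call. = FALSE)
  if (p$n_iterations < 1L)
    stop("n_iterations must be at least 1", call. = FALSE)
  if (p$n_orientations < 2L)
    stop("n_orientations must be at least 2", call. = FALSE)
  if (length(p$canvas) != 2L || any(p$canvas < 8L))
    stop("canvas must be c(width, height), each at least 8 px", call. = FALSE)
  invisible(p)
}

#' Preferred orientations of the channels
#'
#' @param params An `attnet_params` object.
#' @return Numeric vector of channel orientations in radians, evenly spaced
#'   on `[0, pi)`.
#' @export
orientations <- function(params) {
  (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
}

#' Scale the free model parameters by a common factor
#'
#' Multiplies the nine free parameters (all sigmas and alphas, and
#' `sigma_norm`) by `factor`, leaving the stimulus conventions, canvas and
#' iteration count unchanged, and drops any calibrated constants (they must
#' be recalibrated at the new scale). Used by [sensitivity_sweep()].
#'
#' @param params An `attnet_params` object.
#' @param factor Positive multiplier.
#' @return A new `attnet_params` object.
#' @export
scale_params <- function(params, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  for (nm in c("sigma_bottom", "sigma_top", "sigma_inh", "sigma_att_spat",
               "sigma_ori", "alpha_spatial_att", "alpha_feature_att",
               "alpha_fb", "sigma_norm"))
    params[[nm]] <- params[[nm]] * factor
  params$c_bottom <- NULL
  params$c_top <- NULL
  validate_params(params)
  params
}

#' @export
print.attnet_params <- function(x, ...) {
  cat("Two-layer feedback attention network parameters\n")
  cat(sprintf("  sigma: bottom %g, top %g, inh %g, att-spat %g, ori %g rad\n",
              x$sigma_bottom, x$sigma_top, x$sigma_inh, x$sigma_att_spat,
              x$sigma_ori))
  cat(sprintf("  alpha: spatial-att %g, feature-att %g, feedback %g\n",
              x$alpha_spatial_att, x$alpha_feature_att, x$alpha_fb))
  cat(sprintf("  normalization: sigma_norm %g, c_bottom %s, c_top %s\n",
              x$sigma_norm,
              if (is.null(x$c_bottom)) "<uncalibrated>" else
                format(x$c_bottom, digits = 5),
              if (is.null(x$c_top)) "<uncalibrated>" else
                format(x$c_top, digits = 4)))
  cat(sprintf("  %d orientation channels, %d iterations, canvas %dx%d px\n",
              x$n_orientations, x$n_iterations, x$canvas[1], x$canvas[2]))
  invisible(x)
}
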