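# Attention fields: the multiplicative top-down modulation A applied to
# top-layer excitation as (1 + A). Spatial attention is a unit-peak 2-D
# isotropic Gaussian over locations, constant across orientation channels;
# feature attention is a unit-peak Gaussian over circular orientation
# distance, constant across space. The two modes are used one at a time,
# as in every experiment.

attention_field <- function(values, mode, focus = NULL) {
  structure(values, mode = mode, focus = focus, class = "attention_field")
}

#' No attention
#'
#' @param params An [attnet_params()] object.
#' @return An all-zero `attention_field` array
#'   (height x width x n_orientations).
#' @export
no_attention <- function(params) {
  w <- params$canvas[1]; h <- params$canvas[2]
  attention_field(array(0, c(h, w, params$n_orientations)), "none")
}

#' Spatial attention field
#'
#' `A(x) = alpha * exp(-||x - focus||^2 / (2 sigma^2))`, identical in every
#' orientation channel. The peak modulation factor applied to top-layer
#' excitation is therefore `(1 + alpha)^2` after squaring.
#'
#' @param focus Attended location `c(x, y)` in pixels; must lie on the
#'   canvas.
#' @param params An [attnet_params()] object.
#' @param alpha Peak amplitude; defaults to `params$alpha_spatial_att`.
#' @param sigma Field SD in pixels; defaults to `params$sigma_att_spat`.
#'   Overriding it implements the attention-field-size manipulation of the
#'   contrast-response experiment.
#' @return An `attention_field` array.
#' @export
spatial_attention <- function(focus, params,
                              alpha = params$alpha_spatial_att,
                              sigma = params$sigma_att_spat) {
  w <- params$canvas[1]; h <- params$canvas[2]
  if (focus[1] < 1 || focus[1] > w || focus[2] < 1 || focus[2] > h)
    stop("attention focus lies outside the canvas", call. = FALSE)
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - focus[1]
  y <- matrix(seq_len(h), h, w) - focus[2]
  a <- alpha * exp(-(x^2 + y^2) / (2 * sigma^2))
  attention_field(array(rep(a, params$n_orientations),
                        c(h, w, params$n_orientations)),
                  "spatial", focus = focus)
}

#' Circular distance between orientations
#'
#' Orientation is pi-periodic; the distance between two orientations is the
#' smaller of the direct and the wrap-around angular difference.
#'
#' @param a,b Orientations in radians.
#' @return Distance in radians, in `[0, pi/2]`.
#' @export
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Feature (orientation) attention field
#'
#' `A(theta) = alpha * exp(-d(theta, theta_att)^2 / (2 sigma_ori^2))` with
#' `d` the circular orientation distance, identical at every location. The
#' spread equals `sigma_ori`, the orientation spread of the feedforward
#' connections.
#'
#' @param theta_att Attended orientation in radians.
#' @param params An [attnet_params()] object.
#' @param alpha Peak amplitude; defaults to `params$alpha_feature_att`.
#' @return An `attention_field` array.
#' @export
feature_attention <- function(theta_att, params,
                              alpha = params$alpha_feature_att) {
  w <- params$canvas[1]; h <- params$canvas[2]
  a <- alpha * exp(-orientation_distance(orientations(params), theta_att)^2 /
                     (2 * params$sigma_ori^2))
  v <- array(0, c(h, w, params$n_orientations))
  for (k in seq_len(params$n_orientations)) v[, , k] <- a[k]
  attention_field(v, "feature", focus = theta_att)
}
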