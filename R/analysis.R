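# Curve fitting and map statistics used to quantify experiment outputs.

#' Least-squares Gaussian fit
#'
#' Fits `y = baseline + amplitude * exp(-d(x, center)^2 / (2 width^2))` by
#' Nelder-Mead least squares with a deterministic data-driven
#' initialization (peak location and height, half-width at half-height,
#' minimum as baseline). In circular mode `d` is the circular orientation
#' distance on a pi-periodic axis.
#'
#' @param x,y Numeric vectors (at least 4 points).
#' @param circular Treat `x` as pi-periodic orientation.
#' @return List of class `gaussian_fit`: `amplitude`, `center`, `width`,
#'   `baseline`, `rms_residual`, `fitted`.
#' @export
fit_gaussian <- function(x, y, circular = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    stop("cannot fit a Gaussian to a constant curve", call. = FALSE)
  dist_fn <- if (circular) orientation_distance else function(a, b) abs(a - b)
  predict_fn <- function(p) p[4] + p[1] * exp(-dist_fn(x, p[2])^2 / (2 * p[3]^2))
  i0 <- which.max(y)
  base0 <- min(y)
  amp0 <- y[i0] - base0
  half <- y >= base0 + amp0 / 2
  w0 <- max(stats::median(dist_fn(x[half], x[i0])), min(diff(sort(unique(x)))) / 2)
  obj <- function(p) {
    if (p[3] <= 0) return(Inf)
    sum((y - predict_fn(p))^2)
  }
  fit <- stats::optim(c(amp0, x[i0], w0, base0), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- fit$par
  structure(list(amplitude = p[1], center = p[2], width = abs(p[3]),
                 baseline = p[4],
                 rms_residual = sqrt(fit$value / length(y)),
                 fitted = predict_fn(p)),
            class = "gaussian_fit")
}

#' Least-squares Naka-Rushton fit
#'
#' Fits the contrast-response function
#' `r = baseline + r_max * c^n / (c^n + c50^n)` with a deterministic
#' initialization (minimum as baseline, range as `r_max`, half-rise
#' contrast as `c50`, exponent 2).
#'
#' @param contrast,response Numeric vectors (at least 5 points spanning
#'   sub-saturation to saturation).
#' @param monotone_tol Maximum tolerated drop between successive responses,
#'   as a fraction of the response range; larger non-monotonicity is a fit
#'   failure.
#' @return List of class `naka_rushton_fit`: `r_max`, `c50`, `exponent`,
#'   `baseline`, `rms_residual`, `fitted`.
#' @export
fit_naka_rushton <- function(contrast, response, monotone_tol = 0.1) {
  stopifnot(length(contrast) == length(response), length(contrast) >= 5L)
  o <- order(contrast)
  contrast <- contrast[o]; response <- response[o]
  rng <- diff(range(response))
  if (rng <= 0) stop("constant response curve", call. = FALSE)
  if (any(-diff(response) > monotone_tol * rng))
    stop("response curve is non-monotone beyond tolerance", call. = FALSE)
  base0 <- min(response)
  rmax0 <- rng
  c50_0 <- contrast[which.min(abs(response - (base0 + rmax0 / 2)))]
  if (c50_0 <= 0) c50_0 <- max(contrast) / 4
  predict_fn <- function(p)
    p[4] + p[1] * contrast^p[3] / (contrast^p[3] + p[2]^p[3])
  obj <- function(p) {
    if (p[1] <= 0 || p[2] <= 0 || p[3] <= 0) return(Inf)
    sum((response - predict_fn(p))^2)
  }
  fit <- stats::optim(c(rmax0, c50_0, 2, base0), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- fit$par
  structure(list(r_max = p[1], c50 = p[2], exponent = p[3], baseline = p[4],
                 rms_residual = sqrt(fit$value / length(response)),
                 fitted = predict_fn(p)),
            class = "naka_rushton_fit")
}

#' Classify an attentional gain regime
#'
#' Compares attended and unattended Naka-Rushton fits: if the relative
#' change in `r_max` dominates the relative change in `c50` by more than
#' `factor`, the modulation is a response gain; if the reverse, a contrast
#' gain; otherwise mixed.
#'
#' @param fit_att,fit_unatt `naka_rushton_fit` objects.
#' @param factor Dominance ratio (default 2).
#' @return `"response"`, `"contrast"` or `"mixed"`.
#' @export
gain_classification <- function(fit_att, fit_unatt, factor = 2) {
  d_rmax <- abs(fit_att$r_max - fit_unatt$r_max) / fit_unatt$r_max
  d_c50 <- abs(fit_att$c50 - fit_unatt$c50) / fit_unatt$c50
  if (d_rmax > factor * d_c50) "response"
  else if (d_c50 > factor * d_rmax) "contrast"
  else "mixed"
}

#' Receptive-field map statistics
#'
#' Half-max statistics of a probe-grid RF map: the response-weighted
#' centroid of grid points at or above half the peak, the count of such
#' points (RF area in grid cells, with the left/right half-grid
#' breakdown used to localize directional expansion), and the peak
#' response. Coordinates are relative to the grid center, in pixels.
#'
#' @param map An `rf_map` object or plain response matrix.
#' @return List: `centroid` (`c(x, y)`), `area`, `area_left`,
#'   `area_right`, `peak`.
#' @export
rf_statistics <- function(map) {
  m <- unclass(map)
  spacing <- attr(map, "spacing")
  if (is.null(spacing)) spacing <- 1
  if (all(m == 0)) stop("all-zero RF map", call. = FALSE)
  pk <- max(m)
  mask <- m >= pk / 2
  gx <- (col(m) - (ncol(m) + 1) / 2) * spacing
  gy <- (row(m) - (nrow(m) + 1) / 2) * spacing
  w <- m * mask
  list(centroid = c(x = sum(gx * w) / sum(w), y = sum(gy * w) / sum(w)),
       area = sum(mask),
       area_left = sum(mask[gx < 0]), area_right = sum(mask[gx > 0]),
       peak = pk)
}

#' Normalized difference map
#'
#' Pointwise `(a - b) / (a + b)`, bounded in `[-1, 1]`; cells where
#' `a + b = 0` are undefined and returned as `NA`.
#'
#' @param a,b Non-negative numeric arrays of identical shape.
#' @return Numeric array.
#' @export
normalized_difference <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("maps must have identical shape", call. = FALSE)
  s <- a + b
  out <- (a - b) / s
  out[s == 0] <- NA_real_
  out
}
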