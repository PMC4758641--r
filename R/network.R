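# The two-layer recurrent network.
#
# Per iteration:
#   bottom:  E = ((1 + FB) * drive)^2            (modulatory feedback, squaring)
#            R = E / (blur(sum_theta E) + c_bottom)   (divisive normalization)
#   top:     pool = ori_blur(spatial_blur(R_bottom))  (Gaussian pooling)
#            E = ((1 + A) * pool)^2              (attention, squaring)
#            R = E / (blur(sum_theta E) + c_top)
#   feedback: FB = alpha_fb * ori_blur(spatial_blur(R_top))
#
# FB starts at zero and the loop runs a fixed n_iterations passes, which
# suffices to equilibrate responses (verified by the doubled-iteration
# check in the test suite). Spatial blurs use zero padding; the
# orientation blur is circular.

#' Precompute the network operators
#'
#' Builds the Gabor filter bank (as padded FFTs), the separable Gaussian
#' blur matrices and the orientation circulant for a given parameter set,
#' so that repeated stimulus runs share the setup cost.
#'
#' @param params An [attnet_params()] object.
#' @return An object of class `attnet_model`.
#' @export
attnet_model <- function(params) {
  w <- params$canvas[1]; h <- params$canvas[2]
  bank <- gabor_filter_bank(params)
  ksz <- nrow(bank[[1]])
  p1 <- h + ksz - 1L; p2 <- w + ksz - 1L
  bank_fft <- lapply(bank, function(k) {
    kp <- matrix(0, p1, p2); kp[1:ksz, 1:ksz] <- k
    stats::fft(kp)
  })
  m <- list(params = params,
            h = h, w = w, n_ori = params$n_orientations,
            bank = bank, bank_fft = bank_fft, ksz = ksz, p1 = p1, p2 = p2,
            B_inh_r = conv_band_matrix(h, gaussian_kernel_1d(params$sigma_inh)),
            B_inh_c = t(conv_band_matrix(w, gaussian_kernel_1d(params$sigma_inh))),
            B_top_r = conv_band_matrix(h, gaussian_kernel_1d(params$sigma_top)),
            B_top_c = t(conv_band_matrix(w, gaussian_kernel_1d(params$sigma_top))),
            M_ori_t = t(ori_circulant(params$sigma_ori, params$n_orientations)))
  class(m) <- "attnet_model"
  m
}

as_model <- function(x) {
  if (inherits(x, "attnet_model")) x
  else if (inherits(x, "attnet_params")) attnet_model(x)
  else stop("expected attnet_params or attnet_model", call. = FALSE)
}

# blur every orientation channel of a (h*w x n) matrix with the separable
# row/column operators
blur_channels <- function(Xm, Br, Bc, h, w) {
  out <- Xm
  for (k in seq_len(ncol(Xm)))
    out[, k] <- Br %*% matrix(Xm[, k], h, w) %*% Bc
  out
}

#' Feedforward drive of the bottom layer
#'
#' Convolves the image with each oriented Gabor filter and floors negative
#' responses at zero (the drive is an input rate; without rectification,
#' squaring would turn suppression into excitation).
#'
#' @param image Non-negative stimulus matrix matching the model canvas.
#' @param model An [attnet_model()] (or [attnet_params()]).
#' @param rectify Floor negative filter outputs at zero (default). The raw
#'   responses are used internally to shift precomputed probe drives.
#' @return A height x width x n_orientations array.
#' @export
feedforward_drive <- function(image, model, rectify = TRUE) {
  model <- as_model(model)
  if (nrow(image) != model$h || ncol(image) != model$w)
    stop("image size does not match the model canvas", call. = FALSE)
  if (any(image < 0)) stop("stimulus image must be non-negative", call. = FALSE)
  xp <- matrix(0, model$p1, model$p2)
  xp[1:model$h, 1:model$w] <- image
  xf <- stats::fft(xp)
  r <- (model$ksz - 1L) %/% 2L
  out <- array(0, c(model$h, model$w, model$n_ori))
  for (k in seq_len(model$n_ori)) {
    full <- Re(stats::fft(xf * model$bank_fft[[k]], inverse = TRUE)) /
      (model$p1 * model$p2)
    ch <- full[(r + 1L):(r + model$h), (r + 1L):(r + model$w)]
    out[, , k] <- if (rectify) pmax(ch, 0) else ch
  }
  out
}

#' Divisive normalization
#'
#' Untuned short-range normalization: the excitation map is summed over
#' orientation channels, blurred with a Gaussian of SD `sigma_inh`, and
#' every channel is divided by this pooled inhibition plus the constant
#' `c`.
#'
#' @param excitation Non-negative height x width x n_orientations array.
#' @param sigma_inh Inhibition SD in pixels.
#' @param c Positive normalization constant.
#' @return Array of normalized responses, same shape as `excitation`.
#' @export
divisive_normalize <- function(excitation, sigma_inh, c) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("normalization constant c must be positive", call. = FALSE)
  d <- dim(excitation)
  k <- gaussian_kernel_1d(sigma_inh)
  Br <- conv_band_matrix(d[1], k)
  Bc <- t(conv_band_matrix(d[2], k))
  pooled <- rowSums(matrix(excitation, d[1] * d[2], d[3]))
  inh <- Br %*% matrix(pooled, d[1], d[2]) %*% Bc
  sweep_div(excitation, inh, c)
}

sweep_div <- function(excitation, inh, c) {
  d <- dim(excitation)
  m <- matrix(excitation, d[1] * d[2], d[3]) / (as.vector(inh) + c)
  array(m, d)
}

#' Bottom-layer pass
#'
#' Applies the modulatory feedback `(1 + FB)` to the feedforward drive,
#' squares, and normalizes with `(sigma_inh, c_bottom)`.
#'
#' @param drive Rectified feedforward drive array.
#' @param feedback Non-negative feedback array `FB` (same shape); feedback
#'   is strictly excitatory.
#' @param model An [attnet_model()] or [attnet_params()].
#' @param c_bottom Normalization constant; defaults to the calibrated value
#'   stored in the parameters.
#' @return Bottom-layer response array `R`.
#' @export
bottom_pass <- function(drive, feedback, model,
                        c_bottom = as_model(model)$params$c_bottom) {
  model <- as_model(model)
  if (any(feedback < 0))
    stop("feedback must be non-negative (modulatory feedback is strictly excitatory)",
         call. = FALSE)
  if (is.null(c_bottom)) stop("c_bottom is not calibrated", call. = FALSE)
  e <- ((1 + feedback) * drive)^2
  pooled <- rowSums(matrix(e, model$h * model$w, model$n_ori))
  inh <- model$B_inh_r %*% matrix(pooled, model$h, model$w) %*% model$B_inh_c
  sweep_div(e, inh, c_bottom)
}

#' Top-layer pass
#'
#' Pools the bottom-layer response with a spatial Gaussian (SD `sigma_top`)
#' and a circular orientation Gaussian (SD `sigma_ori`), applies the
#' attentional modulation `(1 + A)`, squares, and normalizes with
#' `(sigma_inh, c_top)`.
#'
#' @param bottom_response Bottom-layer response array.
#' @param attention An `attention_field` (or any non-negative array of the
#'   same shape).
#' @param model An [attnet_model()] or [attnet_params()].
#' @param c_top Normalization constant; defaults to the calibrated value.
#' @return Top-layer response array.
#' @export
top_pass <- function(bottom_response, attention, model,
                     c_top = as_model(model)$params$c_top) {
  model <- as_model(model)
  if (any(attention < 0))
    stop("attention field must be non-negative", call. = FALSE)
  if (is.null(c_top)) stop("c_top is not calibrated", call. = FALSE)
  n <- model$h * model$w
  pool <- blur_channels(matrix(bottom_response, n, model$n_ori),
                        model$B_top_r, model$B_top_c, model$h, model$w) %*%
    model$M_ori_t
  e <- (pool * (1 + matrix(attention, n, model$n_ori)))^2
  inh <- model$B_inh_r %*% matrix(rowSums(e), model$h, model$w) %*%
    model$B_inh_c
  array(e / (as.vector(inh) + c_top), c(model$h, model$w, model$n_ori))
}

#' Feedback field
#'
#' The top-to-bottom modulatory field: the top-layer response passed
#' through the same spatial and orientation Gaussian kernels as the
#' feedforward pooling (feedback weights are proportional to the
#' feedforward weights), scaled by `alpha_fb`.
#'
#' @param top_response Top-layer response array.
#' @param model An [attnet_model()] or [attnet_params()].
#' @return Non-negative feedback array `FB`.
#' @export
feedback_field <- function(top_response, model) {
  model <- as_model(model)
  n <- model$h * model$w
  fb <- blur_channels(matrix(top_response, n, model$n_ori),
                      model$B_top_r, model$B_top_c, model$h, model$w) %*%
    model$M_ori_t
  array(model$params$alpha_fb * fb, c(model$h, model$w, model$n_ori))
}

#' Run the network to equilibrium
#'
#' Iterates bottom pass, top pass and feedback computation a fixed
#' `n_iterations` times with the feedback initialized to zero, optionally
#' recording designated probe cells after every iteration.
#'
#' @param image Stimulus matrix on the model canvas, or a precomputed
#'   rectified drive array (height x width x n_orientations).
#' @param attention An `attention_field`; use [no_attention()] for none.
#' @param model An [attnet_model()] or [attnet_params()] with calibrated
#'   constants.
#' @param probes Optional data frame with columns `x`, `y`, `channel`
#'   (1-based), `layer` (`"bottom"` or `"top"`): cells whose activation is
#'   recorded after every iteration.
#' @param n_iterations Override of the configured iteration count.
#' @return An object of class `attnet_state`: list with `bottom_response`,
#'   `top_response`, `feedback` arrays, the per-iteration `traces` matrix
#'   (iterations x probes), and `iterations_run`.
#' @export
run_to_equilibrium <- function(image, attention, model, probes = NULL,
                               n_iterations = NULL) {
  model <- as_model(model)
  p <- model$params
  if (is.null(p$c_bottom) || is.null(p$c_top))
    stop("normalization constants are not calibrated; run calibrate_constants()",
         call. = FALSE)
  niter <- if (is.null(n_iterations)) p$n_iterations else n_iterations
  drive <- if (length(dim(image)) == 3L) image
           else feedforward_drive(image, model)
  n <- model$h * model$w
  dm <- matrix(drive, n, model$n_ori)
  attm <- matrix(attention, n, model$n_ori)
  fb <- matrix(0, n, model$n_ori)
  pidx <- NULL
  if (!is.null(probes))
    pidx <- (probes$channel - 1L) * n + (probes$x - 1L) * model$h + probes$y
  traces <- if (is.null(probes)) NULL else
    matrix(NA_real_, niter, nrow(probes))
  for (it in seq_len(niter)) {
    v1 <- (dm * (1 + fb))^2
    inh <- model$B_inh_r %*% matrix(rowSums(v1), model$h, model$w) %*%
      model$B_inh_c
    v1 <- v1 / (as.vector(inh) + p$c_bottom)
    v4 <- blur_channels(v1, model$B_top_r, model$B_top_c, model$h, model$w) %*%
      model$M_ori_t
    v4 <- (v4 * (1 + attm))^2
    inh4 <- model$B_inh_r %*% matrix(rowSums(v4), model$h, model$w) %*%
      model$B_inh_c
    v4 <- v4 / (as.vector(inh4) + p$c_top)
    fb <- p$alpha_fb *
      (blur_channels(v4, model$B_top_r, model$B_top_c, model$h, model$w) %*%
         model$M_ori_t)
    if (!is.finite(sum(v4)) || !is.finite(sum(v1)))
      stop("network diverged (non-finite values) at iteration ", it,
           call. = FALSE)
    if (!is.null(pidx))
      traces[it, ] <- ifelse(probes$layer == "top", v4[pidx], v1[pidx])
  }
  structure(list(bottom_response = array(v1, c(model$h, model$w, model$n_ori)),
                 top_response = array(v4, c(model$h, model$w, model$n_ori)),
                 feedback = array(fb, c(model$h, model$w, model$n_ori)),
                 traces = traces, probes = probes,
                 iterations_run = niter),
            class = "attnet_state")
}

#' Read a single cell's activation from a network state
#'
#' @param state An `attnet_state`.
#' @param x,y Cell location in pixels (x = column, y = row).
#' @param channel Orientation channel (1-based).
#' @param layer `"top"` or `"bottom"`.
#' @return Scalar activation.
#' @export
probe_response <- function(state, x, y, channel, layer = "top") {
  m <- if (layer == "top") state$top_response else state$bottom_response
  m[y, x, channel]
}

#' Calibrate the normalization constants
#'
#' Runs the equilibrium loop on a calibration stimulus (by default a single
#' full-intensity semi-rectified Gabor at the canvas center, as used in the
#' biased-competition display) with attention off, resetting each layer's
#' constant to `sigma_norm` times that layer's maximum pre-inhibition
#' excitation after every iteration, until both constants change by less
#' than `tol` (relative) over five consecutive iterations (and at least
#' `n_iterations` passes have run, so the constants are read from an
#' equilibrated network). The converged constants are then frozen for all
#' experiments.
#'
#' @param params An [attnet_params()] object.
#' @param calibration_stimulus Optional stimulus matrix; defaults to the
#'   single centered Gabor.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap; non-convergence raises an error.
#' @return The parameters with `c_bottom` and `c_top` set; the convergence
#'   traces are attached as attribute `"trace"` (a two-column matrix).
#' @export
calibrate_constants <- function(params, calibration_stimulus = NULL,
                                tol = 1e-6, max_iter = 500L) {
  model <- attnet_model(params)
  p <- model$params
  if (is.null(calibration_stimulus))
    calibration_stimulus <- stimulus_patch(p, floor((p$canvas + 1) / 2), 0)
  drive <- feedforward_drive(calibration_stimulus, model)
  n <- model$h * model$w
  dm <- matrix(drive, n, model$n_ori)
  fb <- matrix(0, n, model$n_ori)
  cb <- ct <- NA_real_
  stable <- 0L
  trace <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("c_bottom", "c_top")))
  for (it in seq_len(max_iter)) {
    v1 <- (dm * (1 + fb))^2
    cb_new <- p$sigma_norm * max(v1)
    inh <- model$B_inh_r %*% matrix(rowSums(v1), model$h, model$w) %*%
      model$B_inh_c
    v1 <- v1 / (as.vector(inh) + cb_new)
    v4 <- blur_channels(v1, model$B_top_r, model$B_top_c, model$h, model$w) %*%
      model$M_ori_t
    v4 <- v4^2                      # attention off: (1 + 0) factor
    ct_new <- p$sigma_norm * max(v4)
    inh4 <- model$B_inh_r %*% matrix(rowSums(v4), model$h, model$w) %*%
      model$B_inh_c
    v4 <- v4 / (as.vector(inh4) + ct_new)
    fb <- p$alpha_fb *
      (blur_channels(v4, model$B_top_r, model$B_top_c, model$h, model$w) %*%
         model$M_ori_t)
    trace <- rbind(trace, c(cb_new, ct_new))
    ok <- it > 1 && abs(cb_new - cb) <= tol * cb &&
      abs(ct_new - ct) <= tol * ct
    stable <- if (ok) stable + 1L else 0L
    cb <- cb_new; ct <- ct_new
    if (stable >= 5L && it >= p$n_iterations) break
    if (it == max_iter)
      stop("normalization-constant calibration did not converge within ",
           max_iter, " iterations", call. = FALSE)
  }
  params$c_bottom <- cb
  params$c_top <- ct
  attr(params, "trace") <- trace
  params
}

#' Percent attentional modulation
#'
#' `100 * (attended - reference) / reference`, the standard modulation
#' index relative to the no-attention response to the identical display.
#'
#' @param attended,reference Scalar responses (or arrays of equal shape).
#' @return Percent modulation.
#' @export
percent_modulation <- function(attended, reference) {
  100 * (attended - reference) / reference
}
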