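# The in-silico experiments. Every experiment uses the same global
# parameter set and the constants calibrated once on the single-Gabor
# stimulus; only the display and the attention field differ.
#
# Display conventions (the originals are pictorial; these are the
# package's documented choices):
#   * the studied cell is the vertical-preferring top-layer cell at the
#     canvas center (channel 1, theta = 0);
#   * biased competition: one vertical and one horizontal full-intensity
#     Gabor, 10 px left and right of the cell;
#   * RF mapping: two horizontal (anti-preferred) targets at 85% intensity,
#     4/3 sigma_top from the cell ("inside": 16 px at defaults, well within
#     the 3*sigma_top pooling extent) or 2 sigma_top ("edge": 24 px),
#     probed on a 15x15 grid with sigma_top/6 (2 px) spacing; offsets and
#     spacing are RF-relative so the layouts survive parameter scaling.

ensure_calibrated <- function(params) {
  if (is.null(params$c_bottom) || is.null(params$c_top))
    params <- calibrate_constants(params)
  params
}

# studied-cell location: the integer pixel nearest the canvas center
center_of <- function(params) floor((params$canvas + 1) / 2)

# drive of the standard two-target RF display plus a probe at offset
# (dx, dy), computed by shifting a precomputed raw probe drive (linearity
# of convolution) and rectifying the sum
shifted_drive <- function(base_raw, probe_raw, dx, dy) {
  d <- dim(probe_raw)
  pr <- array(0, d)
  sx <- seq_len(d[2]) - dx
  sy <- seq_len(d[1]) - dy
  okx <- sx >= 1 & sx <= d[2]
  oky <- sy >= 1 & sy <= d[1]
  pr[oky, okx, ] <- probe_raw[sy[oky], sx[okx], ]
  pmax(base_raw + pr, 0)
}

#' Biased competition
#'
#' Response of the vertical-preferring top-layer cell to a preferred and an
#' anti-preferred Gabor in its RF, alone and together, with spatial
#' attention on one or the other stimulus. Attention partially restores the
#' response toward the attended stimulus alone without any change in the
#' display.
#'
#' @param params An [attnet_params()] object (calibrated automatically if
#'   needed).
#' @param separation Distance (px) of each stimulus from the cell.
#' @return Data frame of class `condition_table` with columns `condition`,
#'   `response`, `modulation_pct` (percent change vs the no-attention pair
#'   response; 0 by definition for the reference and single-stimulus rows,
#'   `NA` for the singles).
#' @export
biased_competition <- function(params = attnet_params(), separation = 10) {
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  pos_pref <- ctr + c(-separation, 0)
  pos_anti <- ctr + c(separation, 0)
  img_pref <- stimulus_patch(params, pos_pref, 0)
  img_anti <- stimulus_patch(params, pos_anti, pi / 2)
  cell <- function(state) probe_response(state, ctr[1], ctr[2], 1L, "top")
  r_pref <- cell(run_to_equilibrium(img_pref, no_attention(params), model))
  r_anti <- cell(run_to_equilibrium(img_anti, no_attention(params), model))
  pair <- img_pref + img_anti
  r_pair <- cell(run_to_equilibrium(pair, no_attention(params), model))
  r_att_pref <- cell(run_to_equilibrium(pair, spatial_attention(pos_pref, params), model))
  r_att_anti <- cell(run_to_equilibrium(pair, spatial_attention(pos_anti, params), model))
  out <- data.frame(
    condition = c("preferred alone", "anti-preferred alone",
                  "pair, no attention", "pair, attend preferred",
                  "pair, attend anti-preferred"),
    response = c(r_pref, r_anti, r_pair, r_att_pref, r_att_anti),
    modulation_pct = c(NA, NA, 0,
                       percent_modulation(r_att_pref, r_pair),
                       percent_modulation(r_att_anti, r_pair)))
  class(out) <- c("condition_table", "data.frame")
  out
}

#' Layer modulation profile
#'
#' Peak percent attentional modulation in each layer, measured at the cell
#' right under the attentional focus and as the maximum over responsive
#' cells, for either the single-Gabor display (attention on the stimulus)
#' or the biased-competition pair (attention on the preferred stimulus).
#'
#' @param params An [attnet_params()] object.
#' @param display `"single"` or `"pair"`.
#' @param separation Stimulus separation for the pair display.
#' @param active_frac Cells whose no-attention response is below this
#'   fraction of the layer maximum are excluded from the max (percent
#'   change is ill-defined on near-zero responses).
#' @return Named list: `top_at_focus`, `bottom_at_focus`, `top_max`,
#'   `bottom_max` (percent).
#' @export
layer_modulation_profile <- function(params = attnet_params(),
                                     display = c("single", "pair"),
                                     separation = 10, active_frac = 0.02) {
  display <- match.arg(display)
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  if (display == "single") {
    img <- stimulus_patch(params, ctr, 0)
    focus <- ctr
  } else {
    focus <- ctr + c(-separation, 0)
    img <- stimulus_patch(params, focus, 0) +
      stimulus_patch(params, ctr + c(separation, 0), pi / 2)
  }
  s0 <- run_to_equilibrium(img, no_attention(params), model)
  s1 <- run_to_equilibrium(img, spatial_attention(focus, params), model)
  layer_stats <- function(att, ref) {
    sel <- ref >= active_frac * max(ref)
    mod <- percent_modulation(att, ref)
    list(at_focus = mod[focus[2], focus[1], 1L], max = max(mod[sel]))
  }
  top <- layer_stats(s1$top_response, s0$top_response)
  bot <- layer_stats(s1$bottom_response, s0$bottom_response)
  list(top_at_focus = top$at_focus, bottom_at_focus = bot$at_focus,
       top_max = top$max, bottom_max = bot$max)
}

#' Timecourse of attentional modulation
#'
#' Per-iteration activation of orientation-matched probe cells in both
#' layers for a single attended or unattended Gabor, plus the percent
#' modulation trace. Attentional modulation appears earlier and is
#' stronger in the top layer; at iteration 1 the bottom layer is untouched
#' because the feedback starts at zero.
#'
#' @param params An [attnet_params()] object.
#' @return Data frame with columns `iteration`, `bottom_no_att`,
#'   `bottom_att`, `top_no_att`, `top_att`, `bottom_modulation_pct`,
#'   `top_modulation_pct`.
#' @export
timecourse <- function(params = attnet_params()) {
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  img <- stimulus_patch(params, ctr, 0)
  probes <- data.frame(x = ctr[1], y = ctr[2], channel = 1L,
                       layer = c("bottom", "top"))
  s0 <- run_to_equilibrium(img, no_attention(params), model, probes = probes)
  s1 <- run_to_equilibrium(img, spatial_attention(ctr, params), model,
                           probes = probes)
  data.frame(iteration = seq_len(params$n_iterations),
             bottom_no_att = s0$traces[, 1], bottom_att = s1$traces[, 1],
             top_no_att = s0$traces[, 2], top_att = s1$traces[, 2],
             bottom_modulation_pct = percent_modulation(s1$traces[, 1],
                                                        s0$traces[, 1]),
             top_modulation_pct = percent_modulation(s1$traces[, 2],
                                                     s0$traces[, 2]))
}

#' Modulation onset time
#'
#' First iteration at which the absolute modulation reaches half of its
#' final absolute value (a scale-free onset estimate on short traces).
#'
#' @param modulation_trace Numeric per-iteration modulation (percent or
#'   raw). `NaN` entries (0/0 at early iterations) count as zero.
#' @return Integer iteration index.
#' @export
modulation_onset <- function(modulation_trace) {
  m <- abs(modulation_trace)
  m[!is.finite(m)] <- 0
  final <- m[length(m)]
  if (final == 0) return(NA_integer_)
  which(m >= final / 2)[1]
}

#' Orientation tuning under feature-based attention
#'
#' Response of the vertical-preferring cell to a centered Gabor taking all
#' channel orientations, with feature attention always allocated to the
#' stimulus orientation (attended condition) or absent. Feature-similarity
#' gain enhances the response at the preferred orientation and suppresses
#' it at anti-preferred orientations, sharpening the tuning curve.
#'
#' @param params An [attnet_params()] object.
#' @return Data frame: `orientation` (radians), `unattended`, `attended`.
#' @export
orientation_tuning <- function(params = attnet_params()) {
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  th <- orientations(params)
  un <- at <- numeric(length(th))
  for (k in seq_along(th)) {
    img <- stimulus_patch(params, ctr, th[k])
    un[k] <- probe_response(run_to_equilibrium(img, no_attention(params), model),
                            ctr[1], ctr[2], 1L)
    at[k] <- probe_response(run_to_equilibrium(img, feature_attention(th[k], params),
                                               model),
                            ctr[1], ctr[2], 1L)
  }
  data.frame(orientation = th, unattended = un, attended = at)
}

#' Find the saturating stimulus amplitude
#'
#' Marches the amplitude of a single centered Gabor upward until the
#' no-attention probe response grows by less than `tol` (relative) per
#' step.
#' @keywords internal
saturation_amplitude <- function(params, model, tol = 0.01, step = 0.5,
                                 a_max = 16) {
  ctr <- center_of(params)
  cell <- function(a) probe_response(
    run_to_equilibrium(stimulus_patch(params, ctr, 0, amplitude = a),
                       no_attention(params), model), ctr[1], ctr[2], 1L)
  prev <- cell(step)
  a <- step
  while (a < a_max) {
    a <- a + step
    cur <- cell(a)
    if (cur - prev < tol * prev) return(a)
    prev <- cur
  }
  a_max
}

#' Contrast-response curves under attention
#'
#' Response of the studied cell as a function of stimulus amplitude
#' (contrast), without attention and under spatial attention, for either a
#' sweep of attention-field sizes at fixed focus (`"size"`) or a sweep of
#' focus offsets at fixed size (`"offset"`). Shrinking the field yields a
#' response-gain modulation; enlarging it, or moving the focus away from
#' the RF center, yields a contrast-gain modulation, with crossing curves
#' at intermediate offsets.
#'
#' @param params An [attnet_params()] object.
#' @param att_mode `"size"` or `"offset"`.
#' @param levels Attention-field SDs (pixels) for the size sweep (default
#'   1.5 and 12: clearly smaller and larger than the probed RF), or focus
#'   offsets (pixels, along x) for the offset sweep (default 0, 8, 20).
#' @param offset_sigma Attention-field SD held fixed during the offset
#'   sweep; the default small field makes the zero-offset condition a
#'   clean response gain.
#' @param amplitudes Stimulus amplitudes; default 12 levels linear from 0
#'   to the saturation amplitude.
#' @return Data frame: `amplitude`, `no_attention`, then one column per
#'   level (`att_<level>`).
#' @export
contrast_response <- function(params = attnet_params(),
                              att_mode = c("size", "offset"),
                              levels = NULL,
                              offset_sigma = 1.5,
                              amplitudes = NULL) {
  att_mode <- match.arg(att_mode)
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  if (is.null(levels))
    levels <- if (att_mode == "size") c(1.5, 12) else c(0, 8, 20)
  if (is.null(amplitudes))
    amplitudes <- seq(0, saturation_amplitude(params, model), length.out = 12)
  fields <- lapply(levels, function(v) {
    if (att_mode == "size") spatial_attention(ctr, params, sigma = v)
    else spatial_attention(ctr + c(v, 0), params, sigma = offset_sigma)
  })
  cell <- function(img, att) probe_response(
    run_to_equilibrium(img, att, model), ctr[1], ctr[2], 1L)
  out <- data.frame(amplitude = amplitudes)
  out$no_attention <- vapply(amplitudes, function(a)
    cell(stimulus_patch(params, ctr, 0, amplitude = a), no_attention(params)),
    numeric(1))
  for (i in seq_along(levels)) {
    out[[paste0("att_", levels[i])]] <- vapply(amplitudes, function(a)
      cell(stimulus_patch(params, ctr, 0, amplitude = a), fields[[i]]),
      numeric(1))
  }
  attr(out, "att_mode") <- att_mode
  attr(out, "levels") <- levels
  out
}

#' Map a receptive field with a moving probe
#'
#' Two anti-preferred targets at 85% intensity flank the studied cell;
#' a full-intensity preferred probe visits a square grid of positions and
#' the cell's equilibrium response at each position forms the RF map.
#' Attention is focused on a target (or absent). Attending a target inside
#' the RF shifts the RF toward it and shrinks it; attending a target at
#' the RF edge expands the RF toward the focus.
#'
#' @param params An [attnet_params()] object.
#' @param attention `"none"`, `"left"` or `"right"` (focus on that target).
#' @param layout `"inside"` (targets at 4/3 sigma_top, +/-16 px with the
#'   default parameters) or `"edge"` (2 sigma_top, +/-24 px), or a numeric
#'   target offset in pixels. The named layouts scale with `sigma_top`
#'   because "inside" and "edge of" the receptive field are positions
#'   relative to the cell's pooling extent.
#' @param grid_n Grid points per side (odd).
#' @param grid_spacing Grid spacing in pixels; the default `sigma_top / 6`
#'   (2 px with the default parameters) proportions the probe grid to the
#'   RF being mapped. Integer spacings use a fast shifted-drive path;
#'   fractional spacings render each probe position explicitly.
#' @return A `grid_n` x `grid_n` matrix of class `rf_map` with attributes
#'   `spacing`, `condition`, `layout`, `target_offset` (rows = y, columns
#'   = x, probe offsets relative to the cell).
#' @export
map_receptive_field <- function(params = attnet_params(),
                                attention = c("none", "left", "right"),
                                layout = "inside",
                                grid_n = 15,
                                grid_spacing = params$sigma_top / 6) {
  attention <- match.arg(attention)
  params <- ensure_calibrated(params)
  model <- attnet_model(params)
  ctr <- center_of(params)
  off <- if (is.numeric(layout)) layout
         else switch(layout,
                     inside = 4 / 3 * params$sigma_top,
                     edge = 2 * params$sigma_top,
                     stop("unknown layout '", layout, "'", call. = FALSE))
  half <- (grid_n - 1) / 2
  span <- half * grid_spacing
  if (ctr[1] - span < 1 || ctr[1] + span > params$canvas[1] ||
      ctr[2] - span < 1 || ctr[2] + span > params$canvas[2])
    stop("probe grid extends off the canvas", call. = FALSE)
  targets <- stimulus_patch(params, ctr + c(-off, 0), pi / 2, amplitude = 0.85) +
    stimulus_patch(params, ctr + c(off, 0), pi / 2, amplitude = 0.85)
  base_raw <- feedforward_drive(targets, model, rectify = FALSE)
  integer_grid <- isTRUE(all.equal(grid_spacing, round(grid_spacing)))
  probe_raw <- feedforward_drive(stimulus_patch(params, ctr, 0), model,
                                 rectify = FALSE)
  att <- switch(attention,
                none = no_attention(params),
                left = spatial_attention(ctr + c(-off, 0), params),
                right = spatial_attention(ctr + c(off, 0), params))
  m <- matrix(0, grid_n, grid_n)
  for (gy in seq_len(grid_n)) for (gx in seq_len(grid_n)) {
    dx <- (gx - 1 - half) * grid_spacing
    dy <- (gy - 1 - half) * grid_spacing
    drive <- if (integer_grid)
      shifted_drive(base_raw, probe_raw, dx, dy)
    else
      pmax(base_raw +
             feedforward_drive(stimulus_patch(params, ctr + c(dx, dy), 0),
                               model, rectify = FALSE), 0)
    m[gy, gx] <- probe_response(run_to_equilibrium(drive, att, model),
                                ctr[1], ctr[2], 1L)
  }
  structure(m, spacing = grid_spacing, condition = attention,
            layout = if (is.numeric(layout)) "custom" else layout,
            target_offset = off, class = "rf_map")
}

#' Spectral receptive field by reverse correlation
#'
#' Exposes the model to spectrally flat noise patches under feature
#' attention to a given orientation and reconstructs each probe cell's
#' spectral receptive field as the response-weighted average of the
#' patches' 2-D Fourier amplitude spectra (normalized by the summed
#' response). The SRF of an oriented cell is an elongated ellipse along
#' the frequency axis of its preferred orientation; attending an
#' orientation subtly shifts the SRF toward it.
#'
#' @param params An [attnet_params()] object; the canvas should be the
#'   patch size (see `patch_size`).
#' @param theta_att Attended orientation in radians, or `NULL` for no
#'   attention.
#' @param patches List of non-negative square matrices, or `NULL` to
#'   generate `n_patches` whitened-noise patches.
#' @param n_patches,patch_size,seed Patch generation settings when
#'   `patches` is `NULL`.
#' @param channels Probe channels at the patch center (default vertical
#'   and horizontal).
#' @param spectrum `"amplitude"` (default) or `"power"`.
#' @return List of class `srf_map` with one spectrum matrix per channel
#'   (DC at the matrix center), plus `n_patches` and `condition`.
#' @export
spectral_rf <- function(params = NULL, theta_att = NULL, patches = NULL,
                        n_patches = 500, patch_size = 40, seed = 1,
                        channels = c(1L, 5L),
                        spectrum = c("amplitude", "power")) {
  spectrum <- match.arg(spectrum)
  if (is.null(params))
    params <- attnet_params(canvas = c(patch_size, patch_size))
  params <- ensure_calibrated(params)
  if (is.null(patches))
    patches <- whitened_noise_patches(n_patches, params$canvas[1], seed)
  model <- attnet_model(params)
  ctr <- center_of(params)
  att <- if (is.null(theta_att)) no_attention(params)
         else feature_attention(theta_att, params)
  sz <- params$canvas[1]
  acc <- lapply(channels, function(k) matrix(0, sz, sz))
  wsum <- numeric(length(channels))
  fftshift <- function(m) {
    h1 <- floor(nrow(m) / 2)
    m[c((h1 + 1):nrow(m), 1:h1), c((h1 + 1):ncol(m), 1:h1)]
  }
  for (p in patches) {
    st <- run_to_equilibrium(p, att, model)
    sp <- Mod(stats::fft(p))
    if (spectrum == "power") sp <- sp^2
    sp <- fftshift(sp)
    for (i in seq_along(channels)) {
      r <- probe_response(st, ctr[1], ctr[2], channels[i])
      acc[[i]] <- acc[[i]] + r * sp
      wsum[i] <- wsum[i] + r
    }
  }
  if (all(wsum == 0))
    stop("all probe responses are zero; spectral RF is undefined", call. = FALSE)
  srf <- lapply(seq_along(channels), function(i) acc[[i]] / wsum[i])
  names(srf) <- paste0("channel_", channels)
  structure(list(spectra = srf, n_patches = length(patches),
                 condition = if (is.null(theta_att)) "none" else theta_att,
                 channels = channels),
            class = "srf_map")
}

#' Parameter-sensitivity sweep
#'
#' Scales the nine free parameters by a common factor, recalibrates the
#' normalization constants, reruns the qualitative experiments, and
#' reports boolean outcome flags: the biased-competition sign pattern
#' (attend-preferred modulation positive, attend-anti-preferred negative,
#' pair response between the single-stimulus responses), feature-gain
#' sharpening, RF shift toward the attended target, and the RF
#' shrink (inside layout) / expand (edge layout) pattern.
#'
#' @param params An [attnet_params()] object (the unscaled baseline).
#' @param scale_factors Multipliers applied to all free parameters.
#' @param grid_n,grid_spacing RF-map grid used for the RF flags;
#'   `grid_spacing = NULL` (default) uses each scaled parameter set's own
#'   `sigma_top / 6`, matching [map_receptive_field()].
#' @param rf_cache Optional named list (names = scale factors as strings)
#'   of precomputed RF statistics, each a list
#'   `list(inside = list(none =, left =), edge = list(none =, left =))`
#'   of [rf_statistics()] results, to avoid recomputing maps.
#' @param rf_scales Scale factors at which the (expensive) RF-map flags
#'   are computed; at other scales they are `NA`. Defaults to all.
#' @return Data frame: `scale`, `c_bottom`, `c_top`, modulation columns and
#'   the four logical flags.
#' @export
sensitivity_sweep <- function(params = attnet_params(),
                              scale_factors = c(0.8, 1, 1.2),
                              grid_n = 15, grid_spacing = NULL,
                              rf_cache = list(),
                              rf_scales = scale_factors) {
  rows <- lapply(scale_factors, function(f) {
    p <- calibrate_constants(scale_params(params, f))
    bc <- biased_competition(p)
    mods <- bc$modulation_pct[4:5]
    singles <- bc$response[1:2]
    bc_flag <- mods[1] > 0 && mods[2] < 0 &&
      bc$response[3] > min(singles) && bc$response[3] < max(singles)
    tun <- orientation_tuning(p)
    orth <- which.min(abs(tun$orientation - pi / 2))
    fit_u <- fit_gaussian(tun$orientation, tun$unattended, circular = TRUE)
    fit_a <- fit_gaussian(tun$orientation, tun$attended, circular = TRUE)
    fg_flag <- tun$attended[1] > tun$unattended[1] &&
      tun$attended[orth] < tun$unattended[orth] &&
      fit_a$width < fit_u$width
    rf <- rf_cache[[as.character(f)]]
    if (is.null(rf) && f %in% rf_scales)
      rf <- lapply(stats::setNames(c("inside", "edge"), c("inside", "edge")),
                   function(lay)
        lapply(stats::setNames(c("none", "left"), c("none", "left")),
               function(cond)
          rf_statistics(map_receptive_field(
            p, cond, lay, grid_n = grid_n,
            grid_spacing = if (is.null(grid_spacing)) p$sigma_top / 6
                           else grid_spacing))))
    if (is.null(rf)) {
      shift_flag <- NA
      resize_flag <- NA
    } else {
      shift_flag <-
        rf$inside$left$centroid["x"] < rf$inside$none$centroid["x"] &&
        rf$edge$left$centroid["x"] < rf$edge$none$centroid["x"]
      # shrink inside the RF; directional expansion (growth toward the
      # attended edge target) in the edge layout
      resize_flag <- rf$inside$left$area < rf$inside$none$area &&
        rf$edge$left$area_left > rf$edge$none$area_left
    }
    data.frame(scale = f, c_bottom = p$c_bottom, c_top = p$c_top,
               mod_attend_pref = mods[1], mod_attend_anti = mods[2],
               biased_competition = bc_flag, feature_gain = fg_flag,
               rf_shift = shift_flag, rf_resize = resize_flag)
  })
  do.call(rbind, rows)
}
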