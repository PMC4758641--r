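---
title: "A two-layer feedback model of visual attention: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer feedback model of visual attention: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`attnet` simulates two reciprocally connected retinotopic sheets. The
bottom sheet stands in for V1: at every pixel, eight orientation-selective
cells whose feedforward drive is the rectified output of a cosine-phase
Gabor filter bank (orientations 0–157.5° in 22.5° steps, envelope SD
`sigma_bottom` = 3 px). The top sheet stands for intermediate areas such
as V4/MT: its cells have no filters of their own but inherit orientation
selectivity by pooling bottom-layer responses with Gaussian weights over
space (`sigma_top` = 12 px, four times the V1 scale) and over preferred
orientation (`sigma_ori` = 1.1·π/8 rad, circular). Three mechanisms do
all the work:

* **Squaring** of each layer's modulated input, giving an accelerating
  (power-law) single-cell nonlinearity.
* **Divisive normalization** by short-range, orientation-untuned
  inhibition: each cell's squared excitation is divided by a Gaussian
  blur (`sigma_inh` = 1 px) of the orientation-summed excitation plus a
  constant. The inhibition range is deliberately much smaller than either
  layer's RF; this is what scales competitive interactions automatically
  to RF size in each layer.
* **Modulatory feedback**: top-layer responses are sent back through the
  same spatial/orientation Gaussian weights, scaled by `alpha_fb` = 18,
  and multiply (rather than add to) the bottom-layer drive as `(1 + FB)`.
  Attention itself is the same kind of signal applied from outside to the
  top layer only, as `(1 + A)` with a spatial or featural Gaussian
  profile.

The loop runs a fixed 30 passes with FB initialized to zero. Cell
"responses" are instantaneous activation values; there are no spikes, no
noise, no learning, and no outside-RF surround suppression. The model is
therefore silent about spike-train statistics (synchrony, noise
correlations, latency of attentional onset in milliseconds); its
timecourse claims are orderings over iterations, not times.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma_bottom` | 3 | px | V1 filter envelope; sets bottom RF size |
| `sigma_top` | 12 | px | bottom-to-top pooling; sets top RF size |
| `sigma_inh` | 1 | px | range of divisive inhibition, both layers |
| `sigma_att_spat` | 3 | px | spatial attention field SD |
| `sigma_ori` | 1.1·π/8 | rad | orientation pooling and feature-attention spread |
| `alpha_spatial_att` | 2 | – | peak spatial attention amplitude |
| `alpha_feature_att` | 0.2 | – | peak feature attention amplitude |
| `alpha_fb` | 18 | – | feedback strength |
| `sigma_norm` | 0.6 | – | calibration multiplier for the constants |
| `n_iterations` | 30 | – | feedback passes per run |

One global set serves every experiment. `scale_params()` multiplies the
nine free parameters by a common factor for the sensitivity sweep.

### Calibration of the normalization constants

The constants `c_bottom` and `c_top` are not free: they are set by running
the model on a single full-intensity Gabor (the biased-competition
stimulus) and resetting each layer's constant to `sigma_norm` times that
layer's maximum pre-inhibition excitation after every pass, until both are
stable. Because the maximum excitation stabilizes faster than the network
tail, the stopping rule demands five consecutive sub-tolerance steps and
at least the full 30 passes. With the package's conventions the constants
converge to `c_bottom` = 2.0723 and `c_top` = 2.977e-05. This
self-calibration makes every response and modulation invariant to the
overall amplitude convention of the filter bank — rescaling the filters
rescales the constants and nothing else.

## Conventions the equations leave open

The mathematical description leaves several numerical conventions
unstated; the package fixes them once, as follows.

* **Filter normalization.** Each Gabor kernel is DC-corrected (so it
  ignores uniform luminance) and scaled to give response 1 to its own
  unrectified template: drives are in units of the optimal-stimulus
  response. By the invariance above, this choice is cosmetic for all
  modulations and affects only the absolute value of the constants.
* **Kernel conventions.** All Gaussian convolution kernels are unit-sum
  and truncated at radius `ceiling(3*sigma)` (<0.3% mass lost,
  deterministic footprint). Spatial convolutions use zero padding; the
  orientation axis is circular, with truncated weights that alias onto
  the same channel summed. The attention Gaussians are unit-peak, so the
  maximum modulation factor is `(1 + alpha)^2` after squaring; a sum-
  normalized attention field (peak ≈ 0.035) could not produce
  double-digit modulations.
* **Stimulus.** A "semi-rectified Gabor" is `max(0, G)` rendered on a
  zero background, cosine phase (peak at the center), envelope SD 3 px
  and wavelength 6 px — i.e. matched to the bottom-layer filter, making a
  full-intensity patch the optimal stimulus for one channel. The studied
  cell is the vertical-preferring top-layer cell at the canvas center
  (100×100 px, leaving more than `3*sigma_top` of margin so zero padding
  does not contaminate measured RFs).
* **Bottom drive rectification.** Negative filter outputs are floored at
  zero before squaring; without this, strongly suppressive inputs would
  become excitatory under the squaring.
* **Orientation geometry.** Orientation is π-periodic; distances use the
  circular metric `min(|Δ|, π − |Δ|)`. The spatial attention field is an
  isotropic 2-D Gaussian, constant across channels; feature attention is
  constant across space. The two modes are used one at a time, as in
  every experiment.

## Experiment geometry

The published displays are pictorial, so the package fixes explicit
layouts:

* **Biased competition**: preferred (vertical) and anti-preferred
  (horizontal) full-intensity Gabors 10 px left and right of the cell.
  At that separation attention modulates the pair response by ±30%;
  pushing the stimuli much closer (≤8 px) lets the short-range
  normalization saturate the interaction and the biasing collapses.
* **Layer modulation**: measured on the single-Gabor display with the
  focus on the stimulus; the percent modulation right under the focus is
  40% in the top layer and 4.8% in the bottom layer (11.2% at the
  bottom-layer flanks).
* **RF mapping**: two horizontal targets at 85% intensity flank the cell
  at `4/3*sigma_top` (16 px, "inside") or `2*sigma_top` (24 px, "edge");
  a full-intensity vertical probe visits a 15×15 grid with spacing
  `sigma_top/6` (2 px at defaults). Offsets and spacing are expressed in
  units of `sigma_top` because "inside" and "edge of" the RF are
  positions relative to the cell's pooling extent, and an RF is mapped
  with a grid proportioned to it — this matters when the sensitivity
  sweep rescales `sigma_top`. RF statistics are half-max based: the
  response-weighted centroid of grid points at or above half the peak,
  and their count as the RF area, with a left/right breakdown; both are
  standard and robust on a 15×15 grid. The edge-layout expansion is
  directional — the half-max boundary advances on the attended side
  while the far side retreats — so the sensitivity sweep tests the
  attended-side growth, which is the scale-robust signature; the total
  area also grows at the default scale.
* **Contrast curves**: 12 amplitudes, linear from 0 to the level at which
  the no-attention response grows by <1% per 0.5 step. The size sweep
  uses field SDs of 1.5 and 12 px; the offset sweep holds the field at
  1.5 px and moves the focus 0, 8 and 20 px away. With the small field
  the Naka–Rushton fit shows a dominant `r_max` change (response gain);
  with the large field or a distant focus a dominant `c50` change
  (contrast gain); at intermediate offsets the attended and unattended
  curves cross. A "dominant" change means larger by at least a factor 2
  in relative terms — a fixed ratio that makes the qualitative regime
  labels testable.
* **Spectral RFs**: 500 noise patches of 40×40 px; the probe cells sit at
  the patch center and the SRF is the response-weighted mean Fourier
  amplitude spectrum (amplitude rather than power, switchable). The two
  attended orientations, 45° and 135°, are equidistant from both probe
  cells' preferences, so the attentional conditions are exactly
  symmetric. Constants are recalibrated on the patch canvas so the
  operating point stays self-consistent at that size.

## The synthetic noise patches

The spectral-RF experiment needs broadband stimuli with a flat average
spectrum, emulating whitened natural images (the output of retinal
processing). The package generates rectified Gaussian white noise:
its expected power spectrum is flat, while individual patches retain the
spectral fluctuations that reverse correlation exploits — flattening each
patch's spectrum exactly would make the response-weighted average
identical to the unweighted one and the SRF structureless. What these
patches do not emulate is natural-image phase structure (edges, contours)
and higher-order statistics; passing the spectral-RF tests therefore
shows that the reverse-correlation machinery and the attentional shift
work, not that the model reproduces responses to natural scenes.

## Numerical choices

* Convolutions run as FFT products (filter bank) and banded matrix
  products (separable Gaussians); both are checked against direct
  double-loop sums at 1e-10 on small maps.
* The fixed-point iteration converges geometrically, with the slowest
  mode decaying by ≈0.70 per pass: after 30 passes the per-pass change is
  below 1e-3 of the peak response and the residual drift to the exact
  fixed point is below 0.2% — negligible against the ≥5% effects the
  experiments quantify, which is the sense in which 30 passes suffice.
  Probe readout is the single cell at the probe coordinates, no
  averaging.
* Curve fits (Gaussian tuning, Naka–Rushton) use deterministic
  data-driven initialization (peak location/height, half-width at
  half-height, minimum as baseline; half-rise contrast and exponent 2)
  and Nelder–Mead least squares, so fits carry no RNG state. Degenerate
  (constant) curves and strongly non-monotone contrast curves are
  errors, not silent fits.
* Only the noise-patch generator consumes randomness, through an explicit
  seed that leaves the caller's RNG state untouched. Every other result
  is deterministic given the parameters, and `run_experiment()` writes a
  manifest (resolved parameters, constants, seed) sufficient to re-run a
  result bit-identically.

## Sensitivity sweep

`sensitivity_sweep()` multiplies the nine free parameters by a common
factor, recalibrates the constants, and evaluates qualitative flags: the
biased-competition sign pattern (attend-preferred up, attend-anti-
preferred down, pair response between the singles), feature-similarity
sharpening (fitted tuning width narrower under attention, with the right
signs at preferred and orthogonal orientations), RF shift toward the
attended target, and the shrink/expand pattern. At factor 0.8 and 1.0 all
flags hold; at 1.2 the biasing pattern breaks (the attend-anti-preferred
modulation changes sign), while 1.1 still preserves it. The sweep keeps
`n_iterations` at 30 and rescales the stimulus layouts that are defined
relative to `sigma_top`.

## Known limitations

* No temporal dynamics below the granularity of whole-network passes; no
  stochastic firing, so no predictions about variability or correlation.
* No surround suppression: stimuli far outside the RF neither suppress
  nor facilitate beyond what the wide feedback kernels carry.
* The attentional signal is imposed, not computed; the model says nothing
  about how a focus is selected.
* The inside-RF shrink/shift effects depend on the target geometry: with
  targets well inside the half-max RF the short-range normalization
  saturates and attentional structure in the map flattens; the package's
  layouts were chosen where the published sign pattern is robust, and the
  methods above document them explicitly.
* Absolute values of the calibrated constants (and of responses) depend
  on the filter amplitude convention; only their ratios and all percent
  modulations are convention-free.
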