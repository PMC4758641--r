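# Shared fixtures for expensive computations: calibrated parameters,
# receptive-field maps and sweep results are computed once per test run
# and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_params <- function() {
  cached("default_params", calibrate_constants(attnet_params()))
}

default_model <- function() {
  cached("default_model", attnet_model(default_params()))
}

# the five RF maps of the standard mapping protocol
rf_maps <- function() {
  cached("rf_maps", {
    p <- default_params()
    list(inside = list(none = map_receptive_field(p, "none", "inside"),
                       left = map_receptive_field(p, "left", "inside"),
                       right = map_receptive_field(p, "right", "inside")),
          edge = list(none = map_receptive_field(p, "none", "edge"),
                      left = map_receptive_field(p, "left", "edge")))
  })
}

contrast_curves <- function() {
  cached("contrast_curves", {
    p <- default_params()
    list(size = contrast_response(p, "size"),
         offset = contrast_response(p, "offset"))
  })
}

sensitivity_table <- function() {
  cached("sensitivity_table", {
    p <- attnet_params()
    maps <- rf_maps()
    cache_10 <- list(
      inside = lapply(maps$inside[c("none", "left")], rf_statistics),
      edge = lapply(maps$edge[c("none", "left")], rf_statistics))
    sensitivity_sweep(p, scale_factors = c(0.8, 1, 1.2),
                      rf_cache = list("1" = cache_10),
                      rf_scales = c(0.8, 1))
  })
}

srf_pair <- function() {
  cached("srf_pair", {
    list(att45 = spectral_rf(theta_att = pi / 4, n_patches = 500, seed = 11),
         att135 = spectral_rf(theta_att = 3 * pi / 4, n_patches = 500,
                              seed = 11))
  })
}

# mean energy near the carrier-frequency blobs on one frequency axis
# relative to the orthogonal axis; > 1 means the SRF is elongated along
# the cell's preferred-orientation frequency locus
srf_axis_ratio <- function(m, preferred = c("vertical", "horizontal")) {
  preferred <- match.arg(preferred)
  sz <- nrow(m); cc <- sz / 2 + 1
  fx <- matrix(seq_len(sz) - cc, sz, sz, byrow = TRUE)
  fy <- matrix(seq_len(sz) - cc, sz, sz)
  r <- sqrt(fx^2 + fy^2)
  ring <- r >= 4 & r <= 9
  on_fx <- ring & abs(fy) <= 2   # vertical gratings live on the fx axis
  on_fy <- ring & abs(fx) <= 2
  if (preferred == "vertical") mean(m[on_fx]) / mean(m[on_fy])
  else mean(m[on_fy]) / mean(m[on_fx])
}
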