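Package: attnet
Title: Two-Layer Feedback Model of Visual Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-layer recurrent network model of visual
    attention: a V1-like bottom layer of Gabor-filter orientation channels
    and a V4/MT-like top layer that pools the bottom layer over space and
    orientation, with divisive short-range normalization in both layers and
    modulatory (multiplicative) feedback from top to bottom. A top-down
    attentional field, spatial or feature-based, multiplies top-layer
    excitation. The package generates the semi-rectified Gabor stimuli and
    whitened-noise patches used to probe the model, runs the network to
    equilibrium, calibrates the normalization constants, and implements the
    standard in-silico experiments: biased competition, modulation
    timecourse, feature-similarity gain, contrast-response gain regimes,
    spatial receptive-field mapping, spectral receptive-field estimation by
    reverse correlation, and a global parameter-sensitivity sweep. Curve
    fitting (Gaussian tuning, Naka-Rushton contrast response) and
    receptive-field statistics quantify the outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
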