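Package: rfpopmap
Title: Population Orientation-Preference Maps from Non-Oriented Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-computable simulation of visual-neuron populations in mouse
    superficial superior colliculus. Builds center-surround (difference-of-
    Gaussians) and V1-like (Gabor quadrature) receptive fields, renders
    vignetted sinusoidal gratings and moving-bar stimuli, computes rectified
    and energy responses with a baseline-plus-noise response model, warps
    responses from visual-field into anatomical cortical coordinates through a
    natural-neighbor retinotopic transform, pools them into population maps by
    Gaussian smoothing, and derives orientation-preference maps and
    selectivity statistics (gOSI, bar-orientation selectivity, von Mises
    tuning fits). Includes the full set of simulation protocols that
    demonstrate radial and anti-radial aperture-edge orientation preferences
    and their dependence on stimulus spatial frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    png,
    yaml,
    jsonlite,
    tools,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
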