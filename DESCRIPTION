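Package: trsfx
Title: Time-Resolved Crystallography Difference Density and Kinetic Analysis
Version: 0.1.0
Authors@R: person("trsfx", "developers", role = c("aut", "cre"),
    email = "trsfx@example.org")
Description: Tools for time-resolved serial crystallography and in crystallo
    spectroscopy analysis on P1 toy systems: structure-factor calculation by
    direct summation, dataset scaling, isomorphous difference electron density
    (DED) maps with signal-to-noise and low-resolution filtering, masked
    signed density integration, singular value decomposition of DED map
    series, Bayesian (q-) weighted structure-factor extrapolation with
    occupancy estimation from the residual-density inflection, difference-map
    correlation-coefficient (dFoCC) refinement of side-chain reaction
    coordinates, first-order and two-step kinetic fitting on logarithmic time
    grids, and a UV/Vis spectral pipeline (Savitzky-Golay smoothing, Rayleigh
    scattering correction, band integration, Lambert-Beer two-state
    deconvolution). A seeded synthetic-data module generates toy crystals,
    mixed-occupancy reflection datasets, kinetic time series and spectral
    series so the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
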