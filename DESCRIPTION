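Package: mabdev
Title: Biophysical Developability Analysis for Therapeutic Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of antibody developability assays:
    diffusion-interaction-parameter (kD) estimation from dynamic light
    scattering concentration series, generalized Stokes-Einstein theoretical
    viscosity extrapolation, concentration-viscosity model fitting
    (exponential growth, Tomar log-linear, modified Ross-Minton), intrinsic
    viscosity and Huggins-coefficient estimation with first-order error
    propagation, differential scanning fluorimetry transition detection,
    AC-SINS plasmon red-shift analysis, 1:1 Langmuir SPR kinetics, size
    exclusion purity-drift flagging, and homology-model geometric-score
    ranking. Includes seeded synthetic-data generators for every assay
    modality so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
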