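Package: skindose
Title: Rapid Peak Skin Dose Mapping for Fluoroscopically Guided Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs patient skin dose maps for fluoroscopically guided
    interventions by ray tracing the per-event reference air kerma reported
    in the irradiation event log onto a phantom skin grid, with
    inverse-square, backscatter, air-to-tissue mass energy-absorption, and
    table/pad attenuation corrections. Includes an equivalent x-ray spectrum
    model with half-value-layer computation and filtration matching,
    optically stimulated luminescent dosimeter (OSLD) cross-calibration and
    Monte Carlo geometry correction-factor algebra, a validation suite for
    comparing dose maps against OSLD grid measurements, and deterministic
    synthetic scenario generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
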