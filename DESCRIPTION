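Package: mixtk
Title: Toxicokinetic Mixture Analysis for In Vitro Barrier Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro toxicokinetic mixture studies of
    plant protection products and their surface-active co-formulants.
    Fits the four-parameter exponential viability model to cytotoxicity
    dose-response data, derives relative potency factors under a
    parallel-curve assumption and predicts the mixture dose-response under
    concentration addition; reduces bidirectional Caco-2 transwell
    time-series to aliquot-corrected cumulative amounts, apparent
    permeability coefficients and efflux ratios; reduces polarized DPH
    fluorescence intensities to anisotropy and Pgp-Glo ATPase plate
    luminescence to delta-RLU activity contrasts; and provides the
    inferential layer (mixed-effects ANOVA with Dunnett many-to-one
    comparisons, repeated-measures curve contrasts with Holm adjustment).
    A mechanistic synthetic-data generator emulates every assay so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    lme4,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
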