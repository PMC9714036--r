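Package: tcaflux
Title: Stable-Isotope Tracing of TCA-Cycle Fluxes and Tumor Immunogenomic Scoring
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates 13C label propagation through a reduced tricarboxylic-acid
    (TCA) cycle network at positional-isotopomer resolution under glucose, glutamine
    and palmitate tracers; corrects and summarizes mass-isotopologue distributions
    (natural-abundance convolution and deconvolution, enrichment measures); estimates
    relative citrate-synthase flux from label time courses together with anaplerotic
    dilution, a glycolysis readout, steady-state checks and lactate production rates;
    and scores tumor expression cohorts (cytolytic activity, gene-covariate
    correlation screens, differential-expression gating, prognostic Z classification,
    PCA variance, row clustering). Includes seeded synthetic-data generators for
    tracer time courses with measurement noise and for expression cohorts with
    planted, recoverable structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
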