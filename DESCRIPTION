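Package: triageRR
Title: Gage Repeatability and Reproducibility Analysis of Automated
    Disaster Triage Appraisers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how consistently and accurately an automated
    appraiser (for example a large-language-model prompt) assigns Simple
    Triage and Rapid Treatment (START) codes to mass-casualty patient
    vignettes.  Provides a deterministic START flowchart engine, a seeded
    generator for structured synthetic vignette cohorts, stochastic
    confusion-matrix appraiser models with a pluggable callback interface,
    a crossed appraiser-by-part-by-replicate study runner, range-method
    gage repeatability and reproducibility (gage R&R) estimation with
    numerically computed d2 constants, Cohen's kappa for rater agreement,
    and overtriage/undertriage accuracy reporting against an adjudicated
    reference standard.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
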