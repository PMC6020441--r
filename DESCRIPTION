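Package: carrierburden
Title: Weighted Germline Carrier Burden in Unselected Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of unselected cancer cases carrying
    medically actionable germline variants. Implements probabilistic variant
    triage (allele-frequency, clinical-assertion and splice filters;
    truncating, splice, calibrated-prior, functional-assay and in-silico
    consensus weighting rules), per-individual noisy-OR weight combination,
    weighted carrier-frequency estimation with generalized Clopper-Pearson
    intervals, Freeman-Tukey double-arcsine random-effects meta-analysis of
    proportions, and standardized incidence ratios against a reference
    population with exact Poisson inference. Includes a synthetic-data
    generator emulating panel-tested cohorts and a reference population, and
    a packaged fixture of published per-variant carrier weights for
    regression testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
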