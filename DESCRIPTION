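Package: aads
Title: Simulation and Signal Processing for Absorbance-Activated Droplet Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for absorbance-activated droplet sorting
    (AADS) instrumentation. Provides a physics-based simulator of droplet
    photodetector voltage traces (Beer-Lambert absorbance dips, refractive
    index mismatch edge shoulders, photodetector saturation, Gaussian noise),
    a constant-memory streaming peak-detection engine that recovers per-droplet
    absorbance from raw traces, a causal sorting-trigger engine with electrode
    pulse scheduling, a stochastic model of droplet outcomes at the sorting
    junction (fragmentation, false and partial-false sorts), and the
    evaluation statistics used to validate droplet sorters: outcome tallies,
    two-standard-deviation clone classification, true positive rates and
    enrichment factors under both the fraction-ratio and odds-ratio
    conventions. An end-to-end mock-library screening pipeline ties the
    components together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
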