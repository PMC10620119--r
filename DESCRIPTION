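Package: proxhits
Title: Hit Calling for Proximity-Dependent Labeling Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling proximal interactors from proximity-dependent
    labeling mass spectrometry (TurboID/BioID) experiments quantified by
    label-free peak areas and peptide spectral matches. Implements dual-metric
    bait-versus-control enrichment testing with one-tailed pooled-variance
    t-tests and permutation-based false discovery rates, explicit multi-criterion
    hit filtering with funnel reporting, retrospective threshold calibration
    against curated known-interactor sets, interaction-network depth
    stratification of hits around a focal protein, and a synthetic-data
    generator that reproduces the statistical structure of such experiments
    (log-normal intensities, intensity-coupled spectral counts, structural
    zeros in controls, nested batch effects) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
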