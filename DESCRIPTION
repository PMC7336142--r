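Package: brainparcel
Title: Parcel-Based Gray-Matter Morphometry, Permutation Inference and
    Brain-Age Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for parcel-based studies of gray-matter
    volume in aging and dementia cohorts: compression of voxel-wise
    gray-matter maps to atlas parcels, multiple imputation and 1:1
    propensity-score matching with balance diagnostics, parcel-wise n-way
    ANOVA with label-permutation null distributions and set-wise
    maximum-statistic family-wise error correction, and a bagged
    support-vector-regression brain-age ("BrainAGE") ensemble trained on
    stratified subsamples of a heterogeneous reference cohort.  Ships a
    synthetic-cohort simulator that emulates age- and diagnosis-dependent
    atrophy across heterogeneous sites so the full pipeline is testable
    without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
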