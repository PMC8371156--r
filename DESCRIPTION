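Package: cellmorph
Title: Single-Cell Morphological Profiling and Genotype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: High-content-screening style morphological profiling of
    cultured cells. Generates synthetic multichannel fluorescence fields
    and simulated per-cell feature tables with planted cohort structure,
    segments nuclei and cytoplasm, extracts a canonical 124-feature set
    (31 features for each of four markers: basic morphology, intensity,
    symmetry/compactness/axial/radial/profile distribution descriptors,
    and spot/hole/edge/valley texture), normalizes features to negative
    controls per run, scores cells with binary logistic regression,
    aggregates per-individual mean probabilities, performs group tests
    and individual-level ROC analysis, and assesses drug rescue by
    transferring a frozen case-versus-control classifier to treated
    cells with ANOVA and Tukey post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
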