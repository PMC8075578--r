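Package: tectodyn
Title: Spontaneous and Evoked Population Activity Analysis for Larval Zebrafish Tectum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for comparing spontaneous and
    stimulus-evoked population activity in two-photon calcium imaging
    recordings of the larval zebrafish optic tectum. Covers automatic cell
    detection from registered movies, dF/F baseline estimation, SHIFT-null
    significance testing of pairwise correlations, retinotopic tuning-curve
    fits, neural assembly detection and statistics, shuffle-calibrated
    high-coactivity pattern selection, PCA dimensionality, cross-epoch
    cosine similarity, and subspace-projection geometry with balanced
    pattern resampling. Includes a seeded synthetic-data generator with
    ground truth for every stage, so the whole pipeline can be validated by
    parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mclust,
    minpack.lm,
    igraph,
    jsonlite,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
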