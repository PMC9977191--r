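Package: megclust
Title: Covariate-Adjusted Cluster-Based Permutation Tests for Source-Space
    MEG Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting group differences in source-reconstructed
    MEG relative power spectra with a spatio-spectral cluster-based
    permutation test (CBPT) that adjusts each cell-wise comparison for
    nuisance covariates via ANCOVA and controls the family-wise error rate
    with a max-statistic permutation null. Includes multitaper (dpss)
    spectral estimation and relative-power normalisation, regular source
    grids with ROI restriction, a specificity-based biomarker cut point for
    dichotomising cohorts by white-matter-hyperintensity volume,
    cluster-average power markers with Spearman associations to cognitive
    and structural scores, and a synthetic cohort generator with planted
    spatio-spectral effects for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
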