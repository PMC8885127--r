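Package: vasomorph
Title: Microvascular Diameter Dynamics, Vasomotion and Mural-Cell Morphometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cerebral microvascular function from
    two-photon imaging. Extracts per-frame vessel diameter traces by
    full-width-at-half-maximum measurement along a vessel axis, segments
    traces into stimulus-locked trials with locomotion-based rest selection
    and responsiveness classification, quantifies low-frequency vasomotion
    with Welch spectral estimation and 1/f correction, and measures
    mural-cell spacing, marker termination points and branch-point
    specialization on vascular trees. Includes a synthetic-data generator
    producing movies, traces, locomotion and trees with known ground truth,
    and a group-comparison layer (stratified Cochran-Mantel-Haenszel,
    Kruskal-Wallis, ANOVA with Tukey, one-sample tests, Holm-Bonferroni).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Visualization, CellBiology, Spatial
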