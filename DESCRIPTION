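Package: quadstrat
Title: Quadrant Stratification of Plasma Proteomics Cohorts by Inflammation and Neurofilament
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying patient cohorts from Olink-style plasma
    proteomics (NPX) data. Implements panel merging with geometric-mean
    duplicate resolution, QC filtering, per-protein Z-score standardization,
    a 12-protein composite pro-inflammatory score, neurofilament light chain
    (NEFL) classification against a fixed NPX cutoff, percentile-band
    quadrant assignment, the associated battery of association statistics
    (chi-square with pairwise post hoc testing, Kruskal-Wallis with Dunn's
    post hoc, Spearman correlation), correspondence analysis of
    quadrant-by-category contingency tables with Euclidean row-column
    distances, two-group differential protein expression with volcano
    coordinates, and a synthetic-cohort generator for end-to-end testing
    when patient-level data cannot be shared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
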