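Package: tmespatial
Title: Spatial Analysis of the Tumor Immune Microenvironment from Multiplex IHC Cell Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial organisation of immune and tumor
    cells in tissue-microarray cores imaged by multiplex immunohistochemistry.
    Cells are phenotyped from binary marker calls (CD3, CD8, FoxP3, CD163,
    pancytokeratin, PD-L1, granzyme B, Ki67), and per-core spatial statistics
    are computed: nearest-neighbor distances between phenotype pairs,
    engagement within a contact radius, and the cross-type nearest-neighbor
    G-function with Kaplan-Meier edge correction summarised by its area under
    the curve. Cohorts are stratified around the mean HLA-DR positive surface
    area and compared with a normality-gated ANOVA/Wilcoxon battery, Fisher's
    exact test, and Benjamini-Hochberg adjustment. A synthetic cohort
    generator (Poisson and parent-offspring clustered point patterns in
    circular cores) supports calibration and power studies without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
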