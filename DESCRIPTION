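Package: cytodiscover
Title: Differential Discovery in High-Dimensional Cytometry via
    High-Resolution Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential discovery analyses for high-dimensional flow and
    mass cytometry data. Cells are grouped into a large number of small
    clusters with a self-organizing map trained on cell type markers (no
    meta-clustering, so rare populations are not merged away), and
    cluster-level features (cell counts and median cell state marker
    expression) are tested for differential abundance (DA) of populations or
    differential states (DS) within populations. Tests use empirical Bayes
    moderated statistics adapted from transcriptomics (negative binomial
    models with common dispersion, mean-variance precision weights, variance
    squeezing) as well as mixed models (binomial GLMMs with observation-level
    random effects, linear mixed models). Includes a parametric spike-in
    benchmark generator with known ground truth and an evaluation harness
    (ROC, partial AUC, TPR/FDR at FDR cutoffs, null calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    lme4,
    lmerTest,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    pROC,
    ComplexHeatmap,
    grid
Config/testthat/edition: 3
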