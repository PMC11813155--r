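Package: transpred
Title: Transcriptome-Based Prediction of Complex Traits in Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts line-mean phenotypes of inbred panels from gene
    expression profiles. Implements principal-component and wide-kernel
    partial-least-squares regression, ridge and LASSO (via glmnet),
    spike-and-slab Bayesian regression (BayesC) and kernel mixed models
    (TBLUP) fitted by Gibbs sampling, their Gene-Ontology-partitioned
    two-group extensions, and variational spike-and-slab (VARBVS) and
    mixture-of-normals (MR.ASH) regression. Includes a replicated
    train/test evaluation protocol with correlation-based accuracy and
    failure accounting, a per-GO-term prediction scan with top-term gene
    frequency analysis, and a synthetic inbred-panel data generator with
    controlled broad-sense heritability of line means.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
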