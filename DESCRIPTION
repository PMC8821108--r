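Package: hapattern
Title: Histone Acetylation Pattern Discovery and Signature Scoring for
    Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers expression patterns of a histone-acetylation
    regulator gene panel by resampling consensus clustering, derives
    phenotype-related prognostic genes by moderated differential
    expression and univariate Cox screening, quantifies each sample with
    a PCA-based signature score (the HAscore), and associates the score
    with survival, tumor-microenvironment enrichment, epithelial-to-
    mesenchymal transition, and drug sensitivity.  Includes a synthetic
    cohort generator with known latent structure so that every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    limma,
    mclust,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
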