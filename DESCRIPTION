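Package: gradientscope
Title: Connectome Gradient Analysis with Imaging-Transcriptomics Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-level functional connectivity and morphometric
    similarity networks, embeds them into low-dimensional connectivity
    gradients via diffusion map embedding with iterative Procrustes
    alignment, compares groups at the level of canonical resting-state
    networks with effect sizes and analytic noncentral-t power, and relates
    the region-wise group-difference z-map to gene expression through
    single-response partial least squares with a spatial-autocorrelation
    corrected permutation test, bootstrap-corrected gene weights, variable
    importance in projection (VIP) selection, and hypergeometric gene-set
    enrichment. A synthetic-cohort generator with a planted unimodal-to-
    transmodal latent axis makes the entire pipeline testable without any
    neuroimaging or transcriptome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
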