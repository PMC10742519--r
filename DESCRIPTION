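Package: gfabric
Title: Genomic Fabric Analysis of Replicated Transcriptomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes each gene of a replicated expression experiment by
    three independent descriptors: average expression level (AVE), relative
    expression variability (REV, a mid-chi-square interval estimate of the
    coefficient of variation), and pairwise expression coordination (COR,
    Pearson correlation of log2 expressions across biological replicas).
    From these it derives gene-specific adaptive fold-change cut-offs for
    regulation calling, weighted individual and pathway regulation scores
    (WIR/WPR), pathway coordination scores, expression-control regulation,
    transcriptomic distances (TDI), and the gene commanding height (GCH)
    hierarchy with its top-ranked gene master regulator (GMR). Includes a
    probe-level microarray simulator with planted fold changes, per-gene
    coefficients of variation, and correlated gene blocks for validating the
    full pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
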