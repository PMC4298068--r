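Package: eslim
Title: Detection of Alternative Splicing from Exon-Level Expression via
    Gene-Exon Regression Residuals
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects alternative splicing events in exon-level expression
    data (exon microarrays or any log2 feature-by-sample matrix) by
    modelling each exon's signal as a linear function of its gene's signal
    across all samples and testing the regression residuals for
    class-specific shifts with an empirical-Bayes moderated t-test.
    Implements three gene-signal definitions based on how transcripts cover
    the gene locus (all exons, exons common to every transcript, and the
    "gene core": exons common to transcripts spanning at least 60% of the
    locus), probe-to-exon median-polish summarization with quantile
    normalization, a splicing-index baseline, an ROC/AUC benchmarking
    harness against a reference set of known splicing events, and a
    simulator that generates gene models, probe mappings and expression
    matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    limma,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
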