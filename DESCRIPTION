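Package: EndSeqTools
Title: 3'-End RNA-seq Annotation Refinement and Sex-Biased Expression Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QuantSeq-style 3'-end RNA-seq: polyA-aware read
    trimming, discovery of novel polyadenylation sites with internal-priming
    and repeat artifact filters, 3'UTR extension of gene annotations,
    3'-end read counting, removal of unwanted variation with empirical
    control genes, negative binomial differential testing of sex-biased and
    sex-by-age expression, miRNA-target anticorrelation networks,
    co-expression module detection with hub genes and eigengenes, bulk
    deconvolution against a single-cell signature, and cell-weighted
    fold-changes that localize sex-biased expression to cell types.
    Includes a synthetic-data generator with known ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    limma,
    MASS,
    pracma,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
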