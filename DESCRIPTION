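Package: monosomics
Title: Multi-Omics Analysis of Chromosome Loss in Human Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the consequences of monosomy (whole-chromosome
    loss) in somatic human cells from multi-omics data: copy-number calling
    from binned genome coverage, median-shift normalization and log2
    fold-change computation for paired transcriptome/proteome replicates,
    classification of dosage buffering into four mRNA/protein categories,
    rank-based two-dimensional annotation enrichment, single-sample gene set
    enrichment (ssGSEA) pathway scoring, polysome-profile smoothing and
    ribosomal subunit peak quantification, and ploidy-based stratification of
    tumor cohorts with TP53-alteration enrichment. A synthetic-data module
    generates every input with known ground truth so the whole pipeline runs
    and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    signal,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
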