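## Copy-number calling from binned coverage: per-gene median log2 coverage,
## median centering of the whole cell line, then per-chromosome somy calls.

#' Assign coverage bins to genes by interval overlap
#'
#' A bin is assigned to a gene iff their half-open intervals overlap by at
#' least 1 bp; a bin straddling two genes contributes to both. Genes with no
#' overlapping bin are dropped (only genes with at least one mapped coverage
#' are analyzed downstream).
#'
#' @param bins `GRanges` of coverage bins with mcol `coverage`
#'   (non-overlapping per chromosome).
#' @param annotation `GRanges` of gene intervals with mcol `gene_id`.
#' @return Named list (gene_id -> numeric vector of overlapping bin
#'   coverages), omitting genes without bins.
#' @export
assignBinsToGenes <- function(bins, annotation) {
  if (is.null(mcols(bins)$coverage))
    stop("bins must carry a 'coverage' metadata column")
  if (any(mcols(bins)$coverage < 0, na.rm = TRUE))
    stop("coverage values must be >= 0")
  used_gene <- unique(as.character(seqnames(annotation)))
  used_bin <- unique(as.character(seqnames(bins)))
  only_gene <- setdiff(used_gene, used_bin)
  only_bin <- setdiff(used_bin, used_gene)
  if (length(only_gene) || length(only_bin))
    stop("chromosome name mismatch between bins and annotation; ",
         "only in annotation: {", paste(only_gene, collapse = ", "),
         "}; only in bins: {", paste(only_bin, collapse = ", "), "}")
  hits <- findOverlaps(annotation, bins, minoverlap = 1L,
                       ignore.strand = TRUE)
  cov <- split(mcols(bins)$coverage[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_along(annotation)))
  names(cov) <- mcols(annotation)$gene_id
  cov[lengths(cov) > 0]
}

#' Per-gene median log2 coverage
#'
#' Converts each gene's overlapping bin coverages to
#' `log2(coverage + pseudocount)` and takes the median. The pseudocount
#' (default 1) keeps zero-coverage bins finite.
#'
#' @param coverageByGene named list from [assignBinsToGenes()].
#' @param pseudocount added before the log2.
#' @return Named numeric vector gene -> median log2 coverage.
#' @export
perGeneLog2Median <- function(coverageByGene, pseudocount = 1) {
  if (any(vapply(coverageByGene, function(x) any(x < 0), logical(1))))
    stop("coverage values must be >= 0")
  vapply(coverageByGene, function(x) median(log2(x + pseudocount)),
         numeric(1))
}

#' Center per-gene log2 coverage on zero
#'
#' Subtracts the cell-line-wide median so the gene population is centered on
#' 0; a chromosome present at one copy then centers near `log2(1/2) = -1`.
#' Idempotent: centering twice equals centering once.
#'
#' @param log2Values named numeric vector of per-gene log2 coverages.
#' @return Centered vector (same names).
#' @export
centerCoverage <- function(log2Values) {
  if (length(log2Values) == 0) stop("no gene coverage values to center")
  log2Values - median(log2Values)
}

#' Per-gene centered coverage table
#'
#' Convenience wrapper chaining [assignBinsToGenes()], [perGeneLog2Median()]
#' and [centerCoverage()].
#'
#' @inheritParams assignBinsToGenes
#' @inheritParams perGeneLog2Median
#' @return data.frame with columns `gene_id`, `chromosome`, `log2_centered`,
#'   `n_bins` (genes without mapped coverage absent).
#' @export
geneCoverageTable <- function(bins, annotation, pseudocount = 1) {
  cov <- assignBinsToGenes(bins, annotation)
  centered <- centerCoverage(perGeneLog2Median(cov, pseudocount))
  chr <- setNames(as.character(seqnames(annotation)),
                  mcols(annotation)$gene_id)
  data.frame(gene_id = names(centered),
             chromosome = unname(chr[names(centered)]),
             log2_centered = unname(centered),
             n_bins = unname(lengths(cov)),
             stringsAsFactors = FALSE)
}

#' Call per-chromosome somy from centered gene coverage
#'
#' The median centered log2 coverage of a chromosome's genes is compared to
#' two cutoffs: `loss` when median <= `lossCutoff`, `gain` when median >=
#' `gainCutoff`, `neutral` otherwise. Chromosomes with fewer than `minGenes`
#' measured genes are flagged `uncallable` rather than guessed. Because the
#' input is median-centered, calls are invariant to global sequencing depth.
#'
#' @param geneCoverage data.frame from [geneCoverageTable()].
#' @param lossCutoff loss threshold on centered log2 (default -0.5, midpoint
#'   between the copy-1 expectation of -1 and the copy-2 expectation of 0).
#' @param gainCutoff gain threshold (default 0.42).
#' @param minGenes minimum measured genes per chromosome.
#' @return data.frame `chromosome`, `median_log2`, `n_genes`, `call` with
#'   call in `{loss, neutral, gain, uncallable}`, plus the cutoffs used as
#'   attributes.
#' @export
callSomy <- function(geneCoverage, lossCutoff = -0.5, gainCutoff = 0.42,
                     minGenes = 20) {
  stopifnot(lossCutoff < gainCutoff)
  sp <- split(geneCoverage$log2_centered, geneCoverage$chromosome)
  med <- vapply(sp, median, numeric(1))
  n <- lengths(sp)
  call <- ifelse(n < minGenes, "uncallable",
                 ifelse(med <= lossCutoff, "loss",
                        ifelse(med >= gainCutoff, "gain", "neutral")))
  out <- data.frame(chromosome = names(sp), median_log2 = unname(med),
                    n_genes = unname(n), call = unname(call),
                    stringsAsFactors = FALSE)
  attr(out, "lossCutoff") <- lossCutoff
  attr(out, "gainCutoff") <- gainCutoff
  out
}
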