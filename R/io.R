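## Plain-text readers/writers for the pipeline's interchange formats:
## BED (genes), bedGraph (bins), TSV matrices, GMT gene sets, CSV traces,
## TSV cohort tables. BED/bedGraph go through rtracklayer so coordinates are
## 0-based half-open on disk and 1-based closed in memory.

#' Write / read a gene annotation as BED
#'
#' BED6 plus two integer extra columns `is_rpg` and `is_corum`.
#'
#' @param annotation `GRanges` with mcols `gene_id`, `is_rpg`, `is_corum`.
#' @param path output/input file.
#' @return `writeGeneAnnotation` returns `path` invisibly;
#'   `readGeneAnnotation` returns the `GRanges`.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  # BED6+2 by hand: rtracklayer imports extra BED columns but does not
  # export them
  df <- data.frame(chrom = as.character(seqnames(annotation)),
                   start = start(annotation) - 1L,
                   end = end(annotation),
                   name = mcols(annotation)$gene_id,
                   score = 0L, strand = ".",
                   is_rpg = as.integer(mcols(annotation)$is_rpg),
                   is_corum = as.integer(mcols(annotation)$is_corum))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneAnnotation
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(is_rpg = "integer",
                                          is_corum = "integer"))
  mcols(gr) <- DataFrame(gene_id = mcols(gr)$name,
                         is_rpg = as.logical(mcols(gr)$is_rpg),
                         is_corum = as.logical(mcols(gr)$is_corum))
  gr
}

#' Write / read binned coverage as bedGraph
#'
#' @param bins `GRanges` with mcol `coverage`.
#' @param path output/input file.
#' @export
writeBinnedCoverage <- function(bins, path) {
  gr <- bins
  mcols(gr) <- DataFrame(score = mcols(bins)$coverage)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBinnedCoverage
#' @export
readBinnedCoverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  mcols(gr) <- DataFrame(coverage = mcols(gr)$score)
  gr
}

#' Write / read a log2 expression matrix as TSV (genes x replicates)
#'
#' @param mat numeric matrix with gene rownames and replicate colnames, or a
#'   `SummarizedExperiment` with assay `log2`.
#' @param path output/input file.
#' @export
writeExpressionMatrix <- function(mat, path) {
  if (is(mat, "SummarizedExperiment")) mat <- assay(mat, "log2")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write GMT gene-set files
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits the standard
#' tab-separated `term <tab> description <tab> genes...` lines.
#'
#' @param geneSets named list of gene-id character vectors.
#' @param path file path.
#' @export
writeGmt <- function(geneSets, path) {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, nm, geneSets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read a polysome trace as two-column CSV (position, absorbance)
#'
#' @param profile a [PolysomeProfile-class].
#' @param path file path.
#' @param label label for the read profile.
#' @export
writeTrace <- function(profile, path) {
  write.table(data.frame(position = positions(profile),
                         absorbance = absorbance(profile)),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path, label = "") {
  df <- read.table(path, sep = ",", header = TRUE)
  polysomeProfile(df$position, df$absorbance, label = label)
}

#' Write / read a cohort table as TSV
#'
#' @param cohort data.frame (sample, ploidy, tp53_altered, tp53_score,
#'   aneuploidy_score, cancer_type, ...).
#' @param path file path.
#' @export
writeCohortTable <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a FoldChangeTable as TSV
#'
#' Columns: gene, chromosome, mrna_log2fc, protein_log2fc, is_monosomic,
#' is_corum.
#'
#' @param fc a [FoldChangeTable-class].
#' @param path file path.
#' @export
writeFoldChangeTable <- function(fc, path) {
  write.table(as.data.frame(fc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeFoldChangeTable
#' @export
readFoldChangeTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  new("FoldChangeTable", DataFrame(df))
}
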