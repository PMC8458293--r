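## Dosage response: median-shift normalization, fold changes vs the parental
## line, buffering classification at the -0.5 cutoff, pooled medians, CORUM
## comparison and shared extreme proteins.

.assay_log2 <- function(se) {
  m <- assay(se, "log2")
  if (is.null(rownames(m))) stop("expression matrix must have gene rownames")
  m
}

#' Median-shift normalization excluding monosomic genes
#'
#' Each replicate is shifted additively so that its median over the
#' NON-excluded (disomic) genes equals the grand median of those
#' per-replicate medians. Excluded (monosomic) genes receive the same
#' per-replicate shift, so the normalization corrects for the global
#' intensity loss caused by the missing chromosome without pulling monosomic
#' genes toward zero.
#'
#' @param se `SummarizedExperiment` with assay `log2` (genes x replicates).
#' @param exclude character vector of gene ids excluded from the median
#'   computation (a strict subset of the genes).
#' @return The `SummarizedExperiment` with assay `log2` normalized.
#' @export
medianShiftNormalize <- function(se, exclude = character()) {
  m <- .assay_log2(se)
  keep <- !(rownames(m) %in% exclude)
  if (!any(keep))
    stop("exclusion set covers all genes; nothing left to compute medians on")
  med <- apply(m[keep, , drop = FALSE], 2, median)
  target <- median(med)
  m <- sweep(m, 2, med - target)
  SummarizedExperiment::assay(se, "log2") <- m
  se
}

#' Log2 fold change versus the parental line
#'
#' Per gene, the median log2 intensity over the sample's replicates minus the
#' median over the parental replicates. Genes present in only one matrix get
#' `NA`.
#'
#' @param sample,parental `SummarizedExperiment`s with assay `log2`, already
#'   normalized (see [medianShiftNormalize()]).
#' @return Named numeric vector of fold changes over the union of genes.
#' @export
log2FoldChange <- function(sample, parental) {
  ms <- .assay_log2(sample); mp <- .assay_log2(parental)
  shared <- intersect(rownames(ms), rownames(mp))
  if (length(shared) == 0) stop("no shared genes between sample and parental")
  genes <- union(rownames(ms), rownames(mp))
  fc <- setNames(rep(NA_real_, length(genes)), genes)
  meds <- apply(ms[shared, , drop = FALSE], 1, median)
  medp <- apply(mp[shared, , drop = FALSE], 1, median)
  fc[shared] <- meds - medp
  fc
}

#' Build a FoldChangeTable from simulated or imported expression
#'
#' Normalizes all four matrices (excluding monosomic genes from the median),
#' computes fold changes per modality and assembles a [FoldChangeTable-class].
#'
#' @param sim list as returned by [simulateExpression()] (elements
#'   `mrna_sample`, `mrna_parental`, `protein_sample`, `protein_parental`).
#' @param monosome monosomic chromosome labels; defaults to the chromosomes
#'   flagged `monosomic` in the rowData.
#' @return A [FoldChangeTable-class].
#' @export
buildFoldChangeTable <- function(sim, monosome = NULL) {
  rd <- rowData(sim$mrna_sample)
  if (is.null(monosome))
    monosome <- unique(rd$chromosome[rd$monosomic])
  excl <- rd$gene_id[rd$chromosome %in% monosome]
  norm <- lapply(sim[c("mrna_sample", "mrna_parental",
                       "protein_sample", "protein_parental")],
                 medianShiftNormalize, exclude = excl)
  fc_m <- log2FoldChange(norm$mrna_sample, norm$mrna_parental)
  fc_p <- log2FoldChange(norm$protein_sample, norm$protein_parental)
  genes <- rd$gene_id
  FoldChangeTable(gene = genes,
                  chromosome = rd$chromosome,
                  mrna_log2fc = unname(fc_m[genes]),
                  protein_log2fc = unname(fc_p[genes]),
                  monosome = monosome,
                  is_corum = rd$is_corum)
}

#' Per-chromosome median fold-change profile
#'
#' Medians are computed per chromosome and modality on the available
#' (non-missing) values; the monosomic chromosome of a 50%-dosage line sits
#' near -1, disomic chromosomes near 0.
#'
#' @param fc a [FoldChangeTable-class].
#' @return data.frame `chromosome`, `n_genes`, `mrna_median`,
#'   `protein_median`.
#' @export
chromosomeMedianProfile <- function(fc) {
  sp <- split(seq_len(nrow(fc)), fc$chromosome)
  do.call(rbind, lapply(names(sp), function(chr) {
    i <- sp[[chr]]
    data.frame(chromosome = chr, n_genes = length(i),
               mrna_median = median(fc$mrna_log2fc[i], na.rm = TRUE),
               protein_median = median(fc$protein_log2fc[i], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Classify buffering of monosomic genes
#'
#' Operates on matched monosomic genes (both modalities quantified). A
#' modality is "down" when its log2FC <= `cutoff` and "up" when > `cutoff`
#' (values exactly at the cutoff go to the down side). Categories:
#' `up;up` both buffered, `down;up` transcript down / protein buffered,
#' `down;down` neither buffered, `up;down` transcript buffered / protein
#' down.
#'
#' @param fc a [FoldChangeTable-class].
#' @param cutoff log2FC cutoff in (-1, 0), default -0.5.
#' @return A [BufferingResult-class] with per-gene categories, category
#'   fractions and mRNA/protein medians for the matched monosomic and
#'   disomic gene sets.
#' @export
classifyBuffering <- function(fc, cutoff = -0.5) {
  if (cutoff <= -1 || cutoff >= 0) stop("cutoff must lie in (-1, 0)")
  m <- matchedGenes(fc)
  mono <- m[m$is_monosomic, , drop = FALSE]
  if (nrow(mono) == 0) stop("no matched monosomic genes to classify")
  r_down <- mono$mrna_log2fc <= cutoff
  p_down <- mono$protein_log2fc <= cutoff
  cat <- ifelse(!r_down & !p_down, "up;up",
                ifelse(r_down & !p_down, "down;up",
                       ifelse(r_down & p_down, "down;down", "up;down")))
  cat <- factor(cat, levels = BUFFERING_CATEGORIES)
  names(cat) <- mono$gene
  fractions <- as.numeric(table(cat)) / length(cat)
  names(fractions) <- BUFFERING_CATEGORIES
  di <- m[!m$is_monosomic, , drop = FALSE]
  medians <- matrix(
    c(median(mono$mrna_log2fc), median(mono$protein_log2fc),
      median(di$mrna_log2fc), median(di$protein_log2fc)),
    nrow = 2, dimnames = list(c("mrna", "protein"),
                              c("monosomic", "disomic")))
  new("BufferingResult", categories = cat, fractions = fractions,
      medians = medians, cutoff = cutoff)
}

#' Pooled monosome medians across cell lines
#'
#' Combines the matched monosomic gene records of several cell lines
#' (record-level pooling: a gene monosomic in two lines counts twice),
#' excluding the given chromosomes (chromosome X by default, where
#' X-inactivation already silences one copy), and returns the mRNA and
#' protein medians of the pooled set.
#'
#' @param fcList list of [FoldChangeTable-class] objects, one per cell line.
#' @param excludeChromosomes chromosomes dropped before pooling.
#' @return Named numeric `c(mrna = ..., protein = ...)` with attribute
#'   `n_records`.
#' @export
pooledMonosomeMedians <- function(fcList, excludeChromosomes = "chrX") {
  if (!length(fcList)) stop("at least one fold-change table is required")
  recs <- lapply(fcList, function(fc) {
    m <- matchedGenes(fc)
    m <- m[m$is_monosomic & !(m$chromosome %in% excludeChromosomes), ,
           drop = FALSE]
    data.frame(mrna = m$mrna_log2fc, protein = m$protein_log2fc)
  })
  pooled <- do.call(rbind, recs)
  if (nrow(pooled) == 0) stop("no monosomic matched records after exclusion")
  out <- c(mrna = median(pooled$mrna), protein = median(pooled$protein))
  attr(out, "n_records") <- nrow(pooled)
  out
}

#' Protein fold-change shift of CORUM complex subunits
#'
#' Compares the protein log2FC of CORUM-flagged genes with non-CORUM genes,
#' separately on the monosomic and the disomic gene sets, and returns the
#' four medians plus fixed-grid histogram counts (bin width 0.1 over
#' [-3, 3]) for reproducible density summaries.
#'
#' @param fc a [FoldChangeTable-class] with CORUM flags.
#' @return list `medians` (2x2 matrix corum/non_corum x monosomic/disomic),
#'   `histograms` (list of counts on the fixed grid), `breaks`.
#' @export
complexMembershipShift <- function(fc) {
  m <- matchedGenes(fc)
  breaks <- seq(-3, 3, by = 0.1)
  grp <- list(
    monosomic_corum = m$protein_log2fc[m$is_monosomic & m$is_corum],
    monosomic_non_corum = m$protein_log2fc[m$is_monosomic & !m$is_corum],
    disomic_corum = m$protein_log2fc[!m$is_monosomic & m$is_corum],
    disomic_non_corum = m$protein_log2fc[!m$is_monosomic & !m$is_corum])
  if (any(lengths(grp) == 0))
    stop("empty CORUM/non-CORUM group: ",
         paste(names(grp)[lengths(grp) == 0], collapse = ", "))
  medians <- matrix(vapply(grp, median, numeric(1)), nrow = 2, byrow = FALSE,
                    dimnames = list(c("corum", "non_corum"),
                                    c("monosomic", "disomic")))
  hists <- lapply(grp, function(x)
    as.integer(table(cut(pmin(pmax(x, -3), 3), breaks = breaks,
                         include.lowest = TRUE))))
  list(medians = medians, histograms = hists, breaks = breaks)
}

#' Proteins extremely deregulated in several monosomic lines
#'
#' A protein is "up" when its fold change exceeds `threshold` (strictly) in
#' at least `minLines` cell lines, and "down" when it is below `-threshold`
#' in at least `minLines` lines; the direction must be shared, so a protein
#' strongly up in one line and strongly down in another lands in neither
#' list.
#'
#' @param proteinFcByLine named list of named numeric vectors (per cell line,
#'   gene -> protein log2FC).
#' @param threshold positive log2FC threshold (default 1.5).
#' @param minLines minimum number of lines sharing the extreme (default 2).
#' @return list with character vectors `up` and `down` (sorted).
#' @export
sharedExtremeProteins <- function(proteinFcByLine, threshold = 1.5,
                                  minLines = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (length(proteinFcByLine) < minLines)
    stop("need at least ", minLines, " cell lines")
  genes <- unique(unlist(lapply(proteinFcByLine, names)))
  n_up <- n_down <- setNames(integer(length(genes)), genes)
  for (fc in proteinFcByLine) {
    fc <- fc[!is.na(fc)]
    up <- names(fc)[fc > threshold]
    down <- names(fc)[fc < -threshold]
    n_up[up] <- n_up[up] + 1L
    n_down[down] <- n_down[down] + 1L
  }
  list(up = sort(names(n_up)[n_up >= minLines]),
       down = sort(names(n_down)[n_down >= minLines]))
}
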