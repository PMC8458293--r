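#' Buffering category levels
#'
#' Order of the four mRNA/protein buffering categories used throughout:
#' `up;up` (both modalities above the cutoff, i.e. fully buffered),
#' `down;up` (transcript down, protein buffered), `down;down` (neither
#' buffered) and `up;down` (transcript buffered, protein down).
#'
#' @export
BUFFERING_CATEGORIES <- c("up;up", "down;up", "down;down", "up;down")

#' FoldChangeTable: per-gene paired mRNA/protein log2 fold changes
#'
#' A [S4Vectors::DataFrame]-derived table holding, per gene, the log2 fold
#' change versus the parental line at mRNA and protein level (either may be
#' `NA`), the chromosome, and flags for monosomic location and CORUM complex
#' membership. Genes with both modalities quantified form the "matched"
#' subset on which joint analyses (buffering categories, 2D enrichment)
#' operate.
#'
#' @slot .Data,rownames,nrows,listData,elementType,elementMetadata,metadata
#'   inherited from [S4Vectors::DataFrame].
#' @export
setClass("FoldChangeTable", contains = "DFrame")

.fct_required <- c("gene", "chromosome", "mrna_log2fc", "protein_log2fc",
                   "is_monosomic", "is_corum")

setValidity("FoldChangeTable", function(object) {
  miss <- setdiff(.fct_required, colnames(object))
  if (length(miss) > 0)
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$gene))
    return("gene ids must be unique")
  if (!is.logical(object$is_monosomic) || !is.logical(object$is_corum))
    return("is_monosomic and is_corum must be logical")
  if (anyNA(object$is_monosomic))
    return("is_monosomic may not contain NA")
  TRUE
})

#' Construct a FoldChangeTable
#'
#' @param gene character vector of unique gene ids.
#' @param chromosome chromosome (or arm) label per gene.
#' @param mrna_log2fc,protein_log2fc numeric log2 fold changes vs the
#'   parental line; `NA` where a modality was not quantified.
#' @param monosome character vector of chromosome labels declared monosomic;
#'   `is_monosomic` is derived from it.
#' @param is_corum logical flag per gene: product is a subunit of a CORUM
#'   complex.
#' @return A [FoldChangeTable-class] object.
#' @examples
#' fct <- FoldChangeTable(gene = c("a", "b"), chromosome = c("chr1", "chr2"),
#'                        mrna_log2fc = c(-1, 0), protein_log2fc = c(-0.3, 0),
#'                        monosome = "chr1", is_corum = c(TRUE, FALSE))
#' @export
FoldChangeTable <- function(gene, chromosome, mrna_log2fc, protein_log2fc,
                            monosome = character(), is_corum = FALSE) {
  chromosome <- as.character(chromosome)
  is_corum <- rep_len(as.logical(is_corum), length(gene))
  df <- DataFrame(gene = as.character(gene),
                  chromosome = chromosome,
                  mrna_log2fc = as.numeric(mrna_log2fc),
                  protein_log2fc = as.numeric(protein_log2fc),
                  is_monosomic = chromosome %in% as.character(monosome),
                  is_corum = is_corum)
  new("FoldChangeTable", df)
}

#' @describeIn FoldChangeTable Genes quantified in both modalities.
#' @param x,object a `FoldChangeTable`.
#' @export
matchedGenes <- function(x) {
  x[!is.na(x$mrna_log2fc) & !is.na(x$protein_log2fc), , drop = FALSE]
}

#' BufferingResult: per-gene buffering categories and cohort summaries
#'
#' @slot categories factor over [BUFFERING_CATEGORIES], one entry per matched
#'   monosomic gene (names = gene ids).
#' @slot fractions named numeric, fraction of matched monosomic genes per
#'   category (sums to 1).
#' @slot medians numeric matrix `2 x 2` (rows `mrna`/`protein`, columns
#'   `monosomic`/`disomic`) of median log2 fold changes over matched genes.
#' @slot cutoff the log2FC cutoff used (default -0.5).
#' @export
setClass("BufferingResult",
         representation(categories = "factor", fractions = "numeric",
                        medians = "matrix", cutoff = "numeric"))

setValidity("BufferingResult", function(object) {
  if (!identical(levels(object@categories), BUFFERING_CATEGORIES))
    return("category levels must be the four buffering categories")
  if (!isTRUE(all.equal(sum(object@fractions), 1)))
    return("fractions must sum to 1")
  if (!identical(names(object@fractions), BUFFERING_CATEGORIES))
    return("fractions must be named by category")
  if (object@cutoff <= -1 || object@cutoff >= 0)
    return("cutoff must lie in (-1, 0)")
  TRUE
})

#' PolysomeProfile: a UV-absorbance trace along a sucrose gradient
#'
#' Positions are in arbitrary gradient units (monotone increasing);
#' absorbance is the A254-style signal resolving the 40S and 60S subunits,
#' the 80S monosome and the polysome region.
#'
#' @slot position numeric, strictly increasing.
#' @slot absorbance numeric, same length as `position`.
#' @slot label character(1) sample label.
#' @slot smoothed logical(1), whether a Savitzky-Golay filter was applied.
#' @slot window,polyorder smoothing parameters used (NA before smoothing).
#' @slot metadata list, e.g. simulation ground truth.
#' @export
setClass("PolysomeProfile",
         representation(position = "numeric", absorbance = "numeric",
                        label = "character", smoothed = "logical",
                        window = "integer", polyorder = "integer",
                        metadata = "list"))

setValidity("PolysomeProfile", function(object) {
  if (length(object@position) != length(object@absorbance))
    return("position and absorbance must have equal length")
  if (length(object@position) >= 2 && any(diff(object@position) <= 0))
    return("positions must be strictly increasing")
  TRUE
})

#' Construct a PolysomeProfile
#'
#' @param position,absorbance equal-length numeric vectors; positions must be
#'   strictly increasing.
#' @param label sample label.
#' @param metadata optional list (e.g. simulation ground truth).
#' @return A [PolysomeProfile-class] object.
#' @export
polysomeProfile <- function(position, absorbance, label = "", metadata = list()) {
  new("PolysomeProfile", position = as.numeric(position),
      absorbance = as.numeric(absorbance), label = as.character(label),
      smoothed = FALSE, window = NA_integer_, polyorder = NA_integer_,
      metadata = metadata)
}

#' PeakSet: located ribosomal species peaks in a polysome profile
#'
#' @slot species character, `c("40S", "60S", "80S")`.
#' @slot position,height numeric per species (NA when not detected).
#' @slot detected logical per species.
#' @slot windows numeric matrix (one row per species, columns `lo`, `hi`)
#'   of the search windows used.
#' @slot baseline numeric(1), baseline level used for the detection check.
#' @export
setClass("PeakSet",
         representation(species = "character", position = "numeric",
                        height = "numeric", detected = "logical",
                        windows = "matrix", baseline = "numeric"))

setValidity("PeakSet", function(object) {
  n <- length(object@species)
  if (length(object@position) != n || length(object@height) != n ||
      length(object@detected) != n)
    return("species, position, height, detected must be parallel")
  ok <- object@detected
  if (any(ok) && any(object@height[ok] <= object@baseline))
    return("detected peak heights must exceed the baseline")
  if (nrow(object@windows) != n)
    return("one search window per species required")
  w <- object@windows
  if (any(w[, 2] <= w[, 1]))
    return("each window must satisfy lo < hi")
  if (n >= 2 && any(diff(w[, 1]) <= 0))
    return("windows must be ordered along the gradient (40S < 60S < 80S)")
  if (n >= 2 && any(w[-n, 2] > w[-1, 1]))
    return("windows must not overlap")
  TRUE
})
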