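## Single-sample gene set enrichment (ssGSEA) and somy-group comparison.

#' ssGSEA score of one gene set in one sample
#'
#' Genes are ranked by expression (descending; ties broken by gene id for
#' determinism). Walking down the ranking, the score is the sum over all
#' positions of the difference between the weighted in-set empirical CDF and
#' the uniform out-of-set CDF. In-set weights are the absolute expression
#' ranks raised to `alpha` (normalized to sum 1); with `alpha = 0` the in-set
#' CDF is uniform too and the score depends only on gene order. A lower score
#' means the set's genes are under-expressed in this sample.
#'
#' @param expr named numeric vector of expression values for one sample;
#'   must not be constant.
#' @param geneSet character vector of member gene ids; the intersection with
#'   the universe must be non-empty and a strict subset.
#' @param alpha rank weighting exponent >= 0 (default 0.75).
#' @return Numeric score.
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.75) {
  if (is.null(names(expr))) stop("expr must be named by gene")
  if (alpha < 0) stop("alpha must be >= 0")
  n <- length(expr)
  memb_ids <- intersect(geneSet, names(expr))
  if (length(memb_ids) == 0)
    stop("gene set does not intersect the expression universe")
  if (length(memb_ids) == n)
    stop("gene set covers the whole universe")
  if (diff(range(expr)) == 0)
    stop("zero-variance expression vector")
  ord <- order(-expr, names(expr))
  inset <- names(expr)[ord] %in% memb_ids
  r <- rank(expr, ties.method = "average")[ord]  # high expression = high rank
  w <- abs(r)^alpha
  w_in <- w * inset
  cdf_in <- cumsum(w_in) / sum(w_in)
  cdf_out <- cumsum(!inset) / (n - length(memb_ids))
  sum(cdf_in - cdf_out)
}

#' ssGSEA score matrix over samples and gene sets
#'
#' Applies [ssgseaScore()] to every sample and gene set. With
#' `normalize = TRUE` each gene set's scores are divided by their range
#' (max - min) across samples, making scores comparable between sets.
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param geneSets named list of gene-id vectors.
#' @param alpha rank weighting exponent (default 0.75).
#' @param normalize divide each set's scores by their across-sample range.
#' @return samples x gene-sets numeric matrix.
#' @export
scoreMatrix <- function(expr, geneSets, alpha = 0.75, normalize = TRUE) {
  if (normalize && ncol(expr) < 2)
    stop("normalization requires at least two samples")
  s <- vapply(seq_len(ncol(expr)), function(j) {
    v <- setNames(expr[, j], rownames(expr))
    vapply(geneSets, function(gs) ssgseaScore(v, gs, alpha), numeric(1))
  }, numeric(length(geneSets)))
  s <- if (length(geneSets) == 1)
    matrix(s, ncol = 1, dimnames = list(colnames(expr), names(geneSets)))
  else t(matrix(s, nrow = length(geneSets),
                dimnames = list(names(geneSets), colnames(expr))))
  if (normalize) {
    rng <- apply(s, 2, function(x) diff(range(x)))
    rng[rng == 0] <- 1
    s <- sweep(s, 2, rng, "/")
  }
  s
}

#' One-sided Wilcoxon rank-sum comparison of two groups of scores
#'
#' Tests whether the first group's scores are stochastically smaller
#' (`alternative = "less"`) or larger (`"greater"`) than the second group's.
#' The p-value is exact (by enumeration of the rank-sum distribution) when
#' both groups have at most `exactMax` samples and there are no ties, and
#' uses the normal approximation with continuity correction otherwise.
#'
#' @param scores numeric vector of per-sample scores.
#' @param groups factor (or coercible) with exactly two levels aligned with
#'   `scores`; the first level is the first sample of the test.
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param minN minimum group size (default 3).
#' @param exactMax maximum per-group size for the exact p-value (default 12).
#' @return list `p_value`, `n` (named group sizes), `alternative`, `exact`.
#' @export
compareGroups <- function(scores, groups, alternative = "less", minN = 3,
                          exactMax = 12) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2)
    stop("exactly two non-empty groups are required")
  g1 <- scores[groups == levels(groups)[1]]
  g2 <- scores[groups == levels(groups)[2]]
  if (length(g1) < minN || length(g2) < minN)
    stop("both groups must have at least ", minN, " samples")
  ties <- anyDuplicated(c(g1, g2)) > 0
  use_exact <- !ties && max(length(g1), length(g2)) <= exactMax
  p <- suppressWarnings(
    wilcox.test(g1, g2, alternative = alternative, exact = use_exact,
                correct = TRUE)$p.value)
  list(p_value = p,
       n = setNames(c(length(g1), length(g2)), levels(groups)),
       alternative = alternative, exact = use_exact)
}
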