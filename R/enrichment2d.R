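## Rank-based two-dimensional annotation enrichment over paired
## (transcriptome, proteome) fold changes.

#' Average ranks of a numeric vector
#'
#' Thin wrapper around [base::rank()] with average ranks for ties, checking
#' the input is usable for rank-based enrichment.
#'
#' @param values numeric vector (>= 2 finite values).
#' @return Numeric ranks 1..n (ties averaged).
#' @export
rankValues <- function(values) {
  if (sum(is.finite(values)) < 2)
    stop("at least two finite values are required")
  rank(values, ties.method = "average", na.last = "keep")
}

#' Two-dimensional annotation enrichment
#'
#' For each annotation term, genes are split into members and non-members and
#' a rank-based score is computed per dimension:
#' `s = 2 * (mean rank of members - mean rank of non-members) / n`, bounded
#' in [-1, 1]; negative values indicate that the term's genes sit low in that
#' dimension (downregulation). Per-dimension two-sided Mann-Whitney p-values
#' are combined per term as `min(1, 2 * min(p_x, p_y))` (Bonferroni over the
#' two dimensions) and Benjamini-Hochberg FDR is computed across terms. The
#' Mann-Whitney combination is an approximation of the original multivariate
#' 2D test whose exact statistic is not restated here.
#'
#' @param x,y named numeric vectors over the same gene universe (e.g. mRNA
#'   and protein log2FC). Genes missing either value are dropped before
#'   ranking.
#' @param terms named list of character vectors (term -> member gene ids);
#'   terms are intersected with the measured universe before size filtering.
#' @param minSize minimum members after intersection (default 10).
#' @param fdrThreshold BH FDR threshold used when `filter = TRUE`
#'   (default 0.02).
#' @param filter if `TRUE`, only terms with `fdr < fdrThreshold` are
#'   returned.
#' @return data.frame `term`, `n_members`, `score_x`, `score_y`, `p_value`,
#'   `fdr`, sorted by p-value.
#' @export
enrichment2D <- function(x, y, terms, minSize = 10, fdrThreshold = 0.02,
                         filter = TRUE) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("x and y must be named by gene")
  genes <- intersect(names(x)[is.finite(x)], names(y)[is.finite(y)])
  if (length(genes) < 3) stop("too few genes with both values")
  xv <- x[genes]; yv <- y[genes]
  rx <- rankValues(xv); ry <- rankValues(yv)
  n <- length(genes)
  keep <- vapply(terms, function(g) length(intersect(g, genes)) >= minSize,
                 logical(1))
  if (!any(keep)) {
    warning("no term passes the minimum size after intersection")
    return(data.frame(term = character(), n_members = integer(),
                      score_x = numeric(), score_y = numeric(),
                      p_value = numeric(), fdr = numeric()))
  }
  terms <- terms[keep]
  score <- function(r, memb) 2 * (mean(r[memb]) - mean(r[!memb])) / n
  res <- lapply(names(terms), function(tn) {
    memb <- genes %in% terms[[tn]]
    if (all(memb))
      stop("term '", tn, "' covers the whole gene universe (no non-members)")
    px <- suppressWarnings(wilcox.test(xv[memb], xv[!memb])$p.value)
    py <- suppressWarnings(wilcox.test(yv[memb], yv[!memb])$p.value)
    data.frame(term = tn, n_members = sum(memb),
               score_x = score(rx, memb), score_y = score(ry, memb),
               p_value = min(1, 2 * min(px, py)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  if (filter) res <- res[res$fdr < fdrThreshold, , drop = FALSE]
  res
}
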