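## Ploidy-based cohort stratification, TP53-alteration enrichment,
## threshold-sweep robustness and per-cancer-type score comparisons.

.SOMY_LEVELS <- c("Monosomy", "Disomy", "Polysomy")

#' Classify samples into somy strata by ploidy
#'
#' `ploidy < tMono` is Monosomy, `tMono <= ploidy <= tPoly` is Disomy and
#' `ploidy > tPoly` is Polysomy; equality goes to Disomy so a ploidy of
#' exactly 2 is always disomic. Default boundaries 1.80 and 2.19 delimit the
#' disomic range; their robustness is examined with [thresholdSweep()] over
#' [1.66, 1.90] and [2.0, 2.27].
#'
#' @param ploidy positive numeric vector of per-sample ploidies (samples that
#'   underwent whole-genome doubling are assumed removed upstream).
#' @param tMono,tPoly somy boundaries, `tMono < tPoly`.
#' @return Factor with levels Monosomy, Disomy, Polysomy.
#' @export
classifySomy <- function(ploidy, tMono = 1.80, tPoly = 2.19) {
  if (any(!is.finite(ploidy)) || any(ploidy <= 0))
    stop("ploidy values must be positive and finite")
  if (tMono >= tPoly) stop("tMono must be < tPoly")
  cls <- ifelse(ploidy < tMono, "Monosomy",
                ifelse(ploidy <= tPoly, "Disomy", "Polysomy"))
  factor(cls, levels = .SOMY_LEVELS)
}

#' TP53-alteration enrichment in monosomic samples
#'
#' Builds the 2x2 table of somy group (Monosomy vs rest, or Monosomy vs
#' Disomy) against TP53 alteration and tests for enrichment in Monosomy with
#' a one-sided (greater) Fisher's exact test. The reported odds ratio is the
#' sample odds ratio, with a Haldane correction of 0.5 added to every cell
#' when any cell is zero.
#'
#' @param somy factor from [classifySomy()].
#' @param altered logical TP53 alteration flags, aligned with `somy`.
#' @param comparison `"rest"` (Monosomy vs all other samples) or `"disomy"`
#'   (Monosomy vs Disomy only).
#' @return list `table` (2x2), `odds_ratio`, `p_value`.
#' @export
tp53Enrichment <- function(somy, altered, comparison = c("rest", "disomy")) {
  comparison <- match.arg(comparison)
  keep <- if (comparison == "disomy") somy %in% c("Monosomy", "Disomy")
          else rep(TRUE, length(somy))
  somy <- somy[keep]; altered <- as.logical(altered[keep])
  is_mono <- somy == "Monosomy"
  if (all(is_mono) || !any(is_mono))
    stop("both somy groups must be non-empty")
  if (all(altered) || !any(altered))
    stop("both alteration margins must be non-empty")
  tab <- matrix(c(sum(is_mono & altered), sum(is_mono & !altered),
                  sum(!is_mono & altered), sum(!is_mono & !altered)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("Monosomy",
                                          if (comparison == "disomy")
                                            "Disomy" else "Rest"),
                                tp53 = c("altered", "not_altered")))
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, odds_ratio = unname(or), p_value = p)
}

#' Sweep the somy boundaries and re-test TP53 enrichment
#'
#' Evaluates [tp53Enrichment()] at every combination of the candidate
#' monosomy/disomy and disomy/polysomy boundaries; the result is flagged
#' robust when the enrichment is significant at `alpha` at every grid point.
#'
#' @param ploidy,altered per-sample ploidy and TP53 alteration flags.
#' @param tMonoGrid,tPolyGrid candidate boundary values (defaults span
#'   [1.66, 1.90] and [2.0, 2.27]).
#' @param comparison passed to [tp53Enrichment()].
#' @param alpha significance level for the robustness flag.
#' @return data.frame `t_mono`, `t_poly`, `odds_ratio`, `p_value`,
#'   `significant`, with attribute `robust` (logical).
#' @export
thresholdSweep <- function(ploidy, altered,
                           tMonoGrid = seq(1.66, 1.90, by = 0.04),
                           tPolyGrid = seq(2.00, 2.27, by = 0.045),
                           comparison = "disomy", alpha = 0.05) {
  if (any(tMonoGrid >= min(tPolyGrid)))
    stop("every tMono candidate must be below every tPoly candidate")
  grid <- expand.grid(t_mono = tMonoGrid, t_poly = tPolyGrid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cls <- classifySomy(ploidy, grid$t_mono[i], grid$t_poly[i])
    e <- tp53Enrichment(cls, altered, comparison = comparison)
    data.frame(t_mono = grid$t_mono[i], t_poly = grid$t_poly[i],
               odds_ratio = e$odds_ratio, p_value = e$p_value)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha
  attr(out, "robust") <- all(out$significant)
  out
}

#' Per-cancer-type somy-group score comparisons
#'
#' Within each cancer type, compares a score column between somy groups with
#' a one-sided Wilcoxon rank-sum test (default: is the first group's score
#' greater?). Types where either group has fewer than `minN` samples are
#' reported untested. No correction across types by default; set
#' `adjust = "BH"` to add one.
#'
#' @param cohort data.frame with columns `cancer_type`, a somy factor column
#'   `somy`, and the score column.
#' @param scoreColumn name of the score column (e.g. `"tp53_score"`).
#' @param comparisons list of `c(group1, group2)` pairs (default Monosomy vs
#'   Disomy and Polysomy vs Disomy).
#' @param alternative alternative hypothesis for group1 vs group2.
#' @param minN minimum per-group samples within a type (default 3).
#' @param alpha significance level.
#' @param adjust p-value adjustment method across types (default "none").
#' @return list `per_type` (data.frame cancer_type, comparison, n1, n2,
#'   p_value, tested, significant) and `n_significant` (named count per
#'   comparison over tested types).
#' @export
perTypeScoreComparison <- function(cohort, scoreColumn = "tp53_score",
                                   comparisons = list(
                                     c("Monosomy", "Disomy"),
                                     c("Polysomy", "Disomy")),
                                   alternative = "greater", minN = 3,
                                   alpha = 0.05, adjust = "none") {
  stopifnot(all(c("cancer_type", "somy", scoreColumn) %in% colnames(cohort)))
  rows <- list()
  for (cmp in comparisons) {
    lab <- paste(cmp, collapse = ">")
    for (ct in sort(unique(cohort$cancer_type))) {
      sub <- cohort[cohort$cancer_type == ct, ]
      s1 <- sub[[scoreColumn]][sub$somy == cmp[1]]
      s2 <- sub[[scoreColumn]][sub$somy == cmp[2]]
      tested <- length(s1) >= minN && length(s2) >= minN
      p <- if (tested)
        suppressWarnings(wilcox.test(s1, s2,
                                     alternative = alternative)$p.value)
      else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(cancer_type = ct, comparison = lab,
                   n1 = length(s1), n2 = length(s2), p_value = p,
                   tested = tested, stringsAsFactors = FALSE)
    }
  }
  pt <- do.call(rbind, rows)
  if (adjust != "none")
    pt$p_value <- stats::ave(pt$p_value, pt$comparison,
                             FUN = function(p) p.adjust(p, method = adjust))
  pt$significant <- pt$tested & !is.na(pt$p_value) & pt$p_value < alpha
  nsig <- vapply(split(pt$significant, pt$comparison), sum, integer(1))
  list(per_type = pt, n_significant = nsig)
}

#' Aneuploidy-score confounding summary
#'
#' Checks whether TP53 enrichment in Monosomy could be a by-product of
#' overall copy-number burden: summarizes the aneuploidy score (median, IQR)
#' and the TP53 alteration rate per somy class, compares the aneuploidy score
#' between Monosomy and Polysomy with a two-sided rank-sum test, and tests
#' the alteration-rate difference Monosomy vs Polysomy with a one-sided
#' Fisher's exact test.
#'
#' @param cohort data.frame with columns `somy`, `aneuploidy_score`,
#'   `tp53_altered`.
#' @return list `per_class` (data.frame somy, n, median_aneuploidy,
#'   iqr_aneuploidy, alteration_rate), `aneuploidy_p` (Monosomy vs Polysomy,
#'   two-sided) and `alteration_p` (one-sided greater).
#' @export
aneuploidyConfoundSummary <- function(cohort) {
  stopifnot(all(c("somy", "aneuploidy_score", "tp53_altered") %in%
                  colnames(cohort)))
  per <- do.call(rbind, lapply(.SOMY_LEVELS, function(cl) {
    sub <- cohort[cohort$somy == cl, ]
    data.frame(somy = cl, n = nrow(sub),
               median_aneuploidy = median(sub$aneuploidy_score),
               iqr_aneuploidy = IQR(sub$aneuploidy_score),
               alteration_rate = mean(sub$tp53_altered),
               stringsAsFactors = FALSE)
  }))
  mono <- cohort[cohort$somy == "Monosomy", ]
  poly <- cohort[cohort$somy == "Polysomy", ]
  an_p <- suppressWarnings(
    wilcox.test(mono$aneuploidy_score, poly$aneuploidy_score)$p.value)
  tab <- matrix(c(sum(mono$tp53_altered), sum(!mono$tp53_altered),
                  sum(poly$tp53_altered), sum(!poly$tp53_altered)),
                nrow = 2, byrow = TRUE)
  alt_p <- fisher.test(tab, alternative = "greater")$p.value
  list(per_class = per, aneuploidy_p = an_p, alteration_p = alt_p)
}
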