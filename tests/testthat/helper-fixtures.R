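# Shared fixtures and independent oracles. Oracles are deliberately written
# as brute-force enumerations so they share no code path with the package.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# genes x replicates SummarizedExperiment with minimal rowData
makeSE <- function(mat, chromosome = "chr1", monosomic = FALSE,
                   is_corum = FALSE) {
  SummarizedExperiment(
    assays = list(log2 = mat),
    rowData = DataFrame(gene_id = rownames(mat),
                        chromosome = rep_len(chromosome, nrow(mat)),
                        is_rpg = FALSE,
                        is_corum = rep_len(is_corum, nrow(mat)),
                        monosomic = rep_len(monosomic, nrow(mat))))
}

# exact one-sided rank-sum p by enumeration of all group-1 assignments
enumRankSumP <- function(g1, g2, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  n1 <- length(g1)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (alternative == "less") mean(us <= obs) else mean(us >= obs)
}

# exact two-sided Mann-Whitney p by enumeration (no ties assumed)
enumMannWhitneyTwoSided <- function(values, isMember) {
  r <- rank(values)
  m <- sum(isMember)
  obs <- sum(r[isMember]) - m * (m + 1) / 2
  combs <- utils::combn(length(values), m)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# one-sided (greater) Fisher p from the hypergeometric tail
hyperFisherGreaterP <- function(tab) {
  a <- tab[1, 1]
  sum(stats::dhyper(a:min(sum(tab[1, ]), sum(tab[, 1])),
                    sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ])))
}
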