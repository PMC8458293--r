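test_that("median-shift normalization equalizes non-excluded medians", {
  m <- rbind(g1 = c(4, 6), g2 = c(5, 7), g3 = c(6, 8),  # medians 5 and 7
             gx = c(0, 0))                               # excluded gene
  colnames(m) <- c("r1", "r2")
  se <- makeSE(m)
  norm <- assay(medianShiftNormalize(se, exclude = "gx"), "log2")
  expect_equal(unname(apply(norm[c("g1", "g2", "g3"), ], 2, median)),
               c(6, 6))
  # excluded gene shifted by the same per-replicate constant (+1, -1)
  expect_equal(unname(norm["gx", ]), c(1, -1))
  # already-equal medians: identity transform
  m2 <- rbind(g1 = c(1, 1), g2 = c(2, 2), g3 = c(3, 3))
  colnames(m2) <- c("r1", "r2")
  expect_equal(assay(medianShiftNormalize(makeSE(m2)), "log2"), m2)
  expect_error(medianShiftNormalize(se, exclude = rownames(m)), "all genes")
})

test_that("a constant offset on one replicate is undone by normalization", {
  set.seed(31)
  m <- matrix(rnorm(300, 10), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("r", 1:3)))
  se <- makeSE(m)
  base <- assay(medianShiftNormalize(se), "log2")
  m_off <- m
  m_off[, 2] <- m_off[, 2] + 0.8
  off <- assay(medianShiftNormalize(makeSE(m_off)), "log2")
  expect_equal(off, base, tolerance = 1e-12)
})

test_that("log2 fold change is the difference of replicate medians", {
  ms <- matrix(c(9, 9, 9), nrow = 1, dimnames = list("g1", paste0("r", 1:3)))
  mp <- matrix(c(10, 10, 10), nrow = 1,
               dimnames = list("g1", paste0("r", 1:3)))
  expect_equal(log2FoldChange(makeSE(ms), makeSE(mp)), c(g1 = -1))
  set.seed(1)
  m <- matrix(rnorm(30), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("r", 1:3)))
  expect_equal(unname(log2FoldChange(makeSE(m), makeSE(m))), rep(0, 10))
  m2 <- m; rownames(m2) <- sprintf("h%02d", 1:10)
  expect_error(log2FoldChange(makeSE(m), makeSE(m2)), "shared")
})

test_that("pure-dosage simulation recovers the expected -1 median", {
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 1000, seed = 40)
  sim <- simulateExpression(ann, "chrA", probs = c(0, 0, 1, 0),
                            sigmaGene = 0.2, sigmaRep = 0.1, seed = 41)
  fct <- buildFoldChangeTable(sim)
  mono <- fct[fct$is_monosomic, ]
  expect_lt(abs(median(mono$mrna_log2fc) - (-1)), 0.05)
  expect_lt(abs(median(mono$protein_log2fc) - (-1)), 0.05)
  # normalization must not drag monosomic genes toward 0,
  # and disomic genes stay centred on 0
  di <- fct[!fct$is_monosomic, ]
  expect_lt(abs(median(di$mrna_log2fc)), 0.05)
})

test_that("chromosome median profile summarizes per chromosome", {
  fct <- FoldChangeTable(gene = c("a", "b", "c"), chromosome = "chr1",
                         mrna_log2fc = c(-1, -0.5, 0),
                         protein_log2fc = c(-1, -0.5, 0))
  prof <- chromosomeMedianProfile(fct)
  expect_equal(prof$mrna_median, -0.5)
  # mixture simulation: monosome mRNA median in (-1, 0), protein above mRNA
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 800, seed = 42)
  sim <- simulateExpression(ann, "chrA", seed = 43)
  fc <- buildFoldChangeTable(sim)
  prof2 <- chromosomeMedianProfile(fc)
  mono <- prof2[prof2$chromosome == "chrA", ]
  di <- prof2[prof2$chromosome == "chrB", ]
  expect_gt(mono$mrna_median, -1)
  expect_lt(mono$mrna_median, 0)
  expect_gt(mono$protein_median, mono$mrna_median)
  expect_lt(abs(di$mrna_median), 0.05)
})

test_that("buffering categories follow the -0.5 cutoff definitions", {
  fct <- FoldChangeTable(
    gene = c("uu", "du", "dd", "ud", "tie"),
    chromosome = "chr1",
    mrna_log2fc = c(-0.2, -0.8, -0.8, -0.3, -0.5),
    protein_log2fc = c(-0.1, -0.1, -0.9, -0.7, -0.5),
    monosome = "chr1")
  res <- classifyBuffering(fct)
  cats <- categories(res)
  expect_equal(as.character(cats[c("uu", "du", "dd", "ud")]),
               c("up;up", "down;up", "down;down", "up;down"))
  # values exactly at the cutoff go to the down side
  expect_equal(as.character(cats[["tie"]]), "down;down")
  expect_equal(sum(categoryFractions(res)), 1)
  # fractions invariant to gene order
  res2 <- classifyBuffering(fct[5:1, ])
  expect_equal(categoryFractions(res2), categoryFractions(res))
  expect_error(classifyBuffering(fct, cutoff = 0.5), "cutoff")
  di <- FoldChangeTable(gene = "a", chromosome = "chr1", mrna_log2fc = 0,
                        protein_log2fc = 0)
  expect_error(classifyBuffering(di), "monosomic")
})

test_that("mixture fractions are recovered within 3 binomial SE", {
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 2000, seed = 44)
  probs <- c(0.30, 0.45, 0.20, 0.05)
  sim <- simulateExpression(ann, "chrA", probs = probs, seed = 45)
  res <- classifyBuffering(buildFoldChangeTable(sim))
  fr <- categoryFractions(res)
  n <- 2000
  for (i in 1:4)
    expect_lt(abs(fr[[i]] - probs[i]), 3 * sqrt(probs[i] * (1 - probs[i]) / n))
})

test_that("recovered fractions have small mean absolute error across seeds", {
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 2000, seed = 46)
  probs <- c(0.30, 0.45, 0.20, 0.05)
  err <- sapply(1:15, function(s) {
    sim <- simulateExpression(ann, "chrA", probs = probs, sigmaGene = 0.2,
                              seed = 100 + s)
    abs(categoryFractions(classifyBuffering(buildFoldChangeTable(sim))) -
          probs)
  })
  expect_true(all(rowMeans(err) < 0.03))
})

test_that("pooled monosome medians equal brute-force concatenation", {
  one <- FoldChangeTable(gene = "a", chromosome = "chr13",
                         mrna_log2fc = -1, protein_log2fc = -0.2,
                         monosome = "chr13")
  expect_equal(unname(pooledMonosomeMedians(list(one))), c(-1, -0.2),
               ignore_attr = TRUE)
  # two identical tables pool to the same medians (record-level pooling)
  expect_equal(pooledMonosomeMedians(list(one, one)),
               pooledMonosomeMedians(list(one)),
               ignore_attr = TRUE)
  # oracle equivalence on small random tables
  set.seed(47)
  mk <- function(k, chr) FoldChangeTable(
    gene = sprintf("%s_g%d", chr, 1:k), chromosome = chr,
    mrna_log2fc = rnorm(k, -0.6, 0.3), protein_log2fc = rnorm(k, -0.3, 0.3),
    monosome = chr)
  t1 <- mk(11, "chr13"); t2 <- mk(7, "chr10")
  pooled <- pooledMonosomeMedians(list(t1, t2))
  expect_equal(unname(pooled["mrna"]),
               median(c(t1$mrna_log2fc, t2$mrna_log2fc)))
  expect_equal(unname(pooled["protein"]),
               median(c(t1$protein_log2fc, t2$protein_log2fc)))
  expect_equal(attr(pooled, "n_records"), 18)
  # chromosome X is excluded from pooling
  tx <- mk(5, "chrX")
  expect_equal(pooledMonosomeMedians(list(t1, t2, tx)), pooled)
})

test_that("CORUM shift is detected and null shows no spurious shift", {
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 1500, corumFraction = 0.4,
                            seed = 48)
  # null: no CORUM-specific effect
  sim0 <- simulateExpression(ann, "chrA", seed = 49)
  s0 <- complexMembershipShift(buildFoldChangeTable(sim0))
  expect_lt(abs(s0$medians["corum", "monosomic"] -
                  s0$medians["non_corum", "monosomic"]), 0.1)
  # CORUM proteins shifted up by delta on the monosome
  delta <- 0.5
  sim1 <- simulateExpression(ann, "chrA", probs = c(0, 0, 1, 0),
                             corumProteinShift = delta, seed = 50)
  s1 <- complexMembershipShift(buildFoldChangeTable(sim1))
  expect_lt(abs((s1$medians["corum", "monosomic"] -
                   s1$medians["non_corum", "monosomic"]) - delta), 0.1)
  # all flags false: degenerate input
  bad <- FoldChangeTable(gene = c("a", "b"), chromosome = c("chr1", "chr2"),
                         mrna_log2fc = c(0, 0), protein_log2fc = c(0, 0),
                         monosome = "chr1", is_corum = FALSE)
  expect_error(complexMembershipShift(bad), "empty")
})

test_that("shared extreme proteins require strict, same-direction extremes", {
  fcs <- list(l1 = c(p1 = 1.6, p2 = 1.5, p3 = 1.6, p4 = -1.6),
              l2 = c(p1 = 1.7, p2 = 1.6, p3 = -1.6, p4 = -1.7),
              l3 = c(p1 = 0.0, p2 = 0.0, p3 = 0.0, p4 = 0.0))
  out <- sharedExtremeProteins(fcs, threshold = 1.5, minLines = 2)
  expect_equal(out$up, "p1")            # 1.6, 1.7 in two lines
  expect_false("p2" %in% out$up)        # exactly 1.5 is not > 1.5
  expect_false("p3" %in% c(out$up, out$down))  # opposite directions
  expect_equal(out$down, "p4")
  expect_error(sharedExtremeProteins(fcs, threshold = 0), "threshold")
  expect_error(sharedExtremeProteins(fcs[1], minLines = 2), "at least")
})
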