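test_that("simulated annotation is deterministic, sorted and within bounds", {
  chroms <- c(chrA = 1e6, chrB = 1e6, chrC = 1e6, chrD = 1e6, chrE = 1e6)
  ann1 <- simulateAnnotation(chroms, genesPerChromosome = 10,
                             rpgPerChromosome = 1, seed = 7)
  ann2 <- simulateAnnotation(chroms, genesPerChromosome = 10,
                             rpgPerChromosome = 1, seed = 7)
  expect_identical(as.data.frame(ann1), as.data.frame(ann2))
  expect_length(ann1, 50)
  expect_equal(sum(ann1$is_rpg), 5)        # one RPG per chromosome
  expect_true(all(start(ann1) >= 1))
  expect_true(all(end(ann1) <= 1e6))
  # sorted by (chromosome, start) and non-overlapping within chromosome
  df <- as.data.frame(ann1)
  expect_false(is.unsorted(order(df$seqnames, df$start)))
  for (chr in names(chroms)) {
    sub <- df[df$seqnames == chr, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$end[-nrow(sub)] < sub$start[-1]))
  }
  # RPG exclusion set honoured
  ann3 <- simulateAnnotation(chroms, genesPerChromosome = 10,
                             rpgPerChromosome = 1, rpgExclude = "chrB",
                             seed = 7)
  expect_equal(sum(ann3$is_rpg[as.character(seqnames(ann3)) == "chrB"]), 0)
  expect_equal(sum(ann3$is_rpg), 4)
})

test_that("degenerate annotation configurations are rejected", {
  expect_error(simulateAnnotation(numeric(0)), "chromosome")
  expect_error(simulateAnnotation(c(chrA = 1e6), genesPerChromosome = 0),
               "gene")
  expect_error(simulateAnnotation(c(chrA = 1e6), corumFraction = 2),
               "corumFraction")
})

test_that("read depth scales with copy number and is exact without noise", {
  ann <- simulateAnnotation(c(chrA = 1e6, chrB = 1e6),
                            genesPerChromosome = 10, seed = 1)
  bins <- simulateReadDepth(ann, binSize = 1e5, meanDepth = 80,
                            dispersion = NULL)
  expect_true(all(bins$coverage == 80))
  bins1 <- simulateReadDepth(ann, karyotype = c(chrA = 1L), binSize = 1e5,
                             meanDepth = 80, dispersion = NULL)
  covA <- bins1$coverage[as.character(seqnames(bins1)) == "chrA"]
  covB <- bins1$coverage[as.character(seqnames(bins1)) == "chrB"]
  expect_true(all(covA == 40))
  expect_true(all(covB == 80))
  expect_error(simulateReadDepth(ann, karyotype = c(chrZ = 1L)), "chrZ")
  expect_error(simulateReadDepth(ann, binSize = 0), "binSize")
})

test_that("noisy read depth has the right mean (Monte Carlo, 3 SE)", {
  ann <- simulateAnnotation(c(chrA = 1e8), genesPerChromosome = 10, seed = 1)
  disp <- 0.05
  bins <- simulateReadDepth(ann, karyotype = c(chrA = 1L), binSize = 1e4,
                            meanDepth = 100, dispersion = disp, seed = 11)
  expect_equal(length(bins), 1e4)
  mu <- 50
  se <- sqrt((mu + disp * mu^2) / length(bins))
  expect_lt(abs(mean(bins$coverage) - mu), 3 * se)
  # determinism
  bins2 <- simulateReadDepth(ann, karyotype = c(chrA = 1L), binSize = 1e4,
                             meanDepth = 100, dispersion = disp, seed = 11)
  expect_identical(bins$coverage, bins2$coverage)
})

test_that("degenerate buffering mixtures give exact dosage offsets", {
  ann <- simulateAnnotation(c(chrA = 1e6, chrB = 1e6),
                            genesPerChromosome = 50, seed = 2)
  # all mass on down;down, no noise: every monosomic gene at (-1, -1)
  sim <- simulateExpression(ann, "chrA", probs = c(0, 0, 1, 0),
                            sigmaGene = 0, sigmaRep = 0, seed = 3)
  fc_m <- log2FoldChange(sim$mrna_sample, sim$mrna_parental)
  fc_p <- log2FoldChange(sim$protein_sample, sim$protein_parental)
  mono <- rowData(sim$mrna_sample)$monosomic
  gid <- rowData(sim$mrna_sample)$gene_id
  expect_equal(unname(fc_m[gid[mono]]), rep(-1, sum(mono)))
  expect_equal(unname(fc_p[gid[mono]]), rep(-1, sum(mono)))
  expect_equal(unname(fc_m[gid[!mono]]), rep(0, sum(!mono)))
  # all mass on up;up: centred at (0, 0)
  sim2 <- simulateExpression(ann, "chrA", probs = c(1, 0, 0, 0),
                             sigmaGene = 0, sigmaRep = 0, seed = 3)
  fc2 <- log2FoldChange(sim2$mrna_sample, sim2$mrna_parental)
  expect_equal(unname(fc2[gid[mono]]), rep(0, sum(mono)))
  expect_error(simulateExpression(ann, character(0)), "empty")
  expect_error(simulateExpression(ann, "chrZ"), "chrZ")
  expect_error(simulateExpression(ann, "chrA", probs = c(1, 1, 0, 0)),
               "probs")
})

test_that("mixture category counts match multinomial expectation (3 SE)", {
  ann <- simulateAnnotation(c(chrA = 6e7, chrB = 6e7),
                            genesPerChromosome = 2000, seed = 4)
  probs <- c(0.30, 0.45, 0.20, 0.05)
  sim <- simulateExpression(ann, "chrA", probs = probs, seed = 5)
  counts <- table(sim$truth$category)
  n <- sum(counts)
  expect_equal(n, 2000)
  for (i in 1:4) {
    se <- sqrt(n * probs[i] * (1 - probs[i]))
    expect_lt(abs(counts[[i]] - n * probs[i]), 3 * se)
  }
  # determinism of the whole output
  sim2 <- simulateExpression(ann, "chrA", probs = probs, seed = 5)
  expect_identical(assay(sim$mrna_sample, "log2"),
                   assay(sim2$mrna_sample, "log2"))
  expect_identical(sim$truth, sim2$truth)
})

test_that("polysome trace generator places peaks where asked", {
  # single noise-free peak: maximum = baseline + height at the peak position
  tr <- simulatePolysomeTrace(peakPositions = 50, peakHeights = 0.8,
                              peakWidths = 3, baseline = 0.1, noiseSd = 0,
                              nPoints = 1001)
  i <- which.max(absorbance(tr))
  expect_equal(positions(tr)[i], 50)
  expect_equal(max(absorbance(tr)), 0.9, tolerance = 1e-10)
  # two well-separated peaks: local maxima ratio equals the height ratio
  tr2 <- simulatePolysomeTrace(peakPositions = c(25, 75),
                               peakHeights = c(0.4, 0.2),
                               peakWidths = c(2, 2), baseline = 0,
                               noiseSd = 0, nPoints = 2001)
  y <- absorbance(tr2); x <- positions(tr2)
  h1 <- max(y[x < 50]); h2 <- max(y[x >= 50])
  expect_equal(h1 / h2, 2, tolerance = 1e-6)
  # determinism and argument checking
  ta <- simulatePolysomeTrace(noiseSd = 0.02, seed = 9)
  tb <- simulatePolysomeTrace(noiseSd = 0.02, seed = 9)
  expect_identical(absorbance(ta), absorbance(tb))
  expect_error(simulatePolysomeTrace(peakWidths = c(0, 2, 2, 2)), "width")
  expect_error(simulatePolysomeTrace(peakPositions = c(30, 20, 42, 62)),
               "increasing")
})

test_that("cohort generator hits its stratum fractions and null structure", {
  coh <- simulateCohort(nSamples = 1000, somyFractions = c(0.1, 0.8, 0.1),
                        seed = 6)
  counts <- table(coh$cohort$somy_truth)
  for (i in seq_along(counts)) {
    p <- c(0.1, 0.8, 0.1)[i]
    expect_lt(abs(counts[[i]] - 1000 * p), 3 * sqrt(1000 * p * (1 - p)))
  }
  expect_true(all(coh$cohort$ploidy > 0))
  expect_equal(dim(coh$expression), c(500, 1000))
  # equal alteration probability across strata: odds ratio near 1
  null <- simulateCohort(nSamples = 20000,
                         tp53AltProb = c(0.35, 0.35, 0.35), seed = 7)
  e <- tp53Enrichment(null$cohort$somy_truth, null$cohort$tp53_altered)
  expect_gt(e$odds_ratio, 0.85)
  expect_lt(e$odds_ratio, 1.15)
  expect_error(
    simulateCohort(nSamples = 10, pathwayGeneSets = list(bad = "nope"),
                   seed = 1),
    "universe")
})
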