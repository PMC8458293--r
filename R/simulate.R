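## Synthetic-data generators. Every generator takes an explicit `seed` and is
## byte-deterministic under it; ground truth is returned alongside the data so
## downstream stages can be tested as parameter-recovery problems.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Simulate a gene annotation
#'
#' Generates non-overlapping gene intervals on a small synthetic genome, with
#' ribosomal-protein-gene (RPG) and CORUM complex-membership flags. Mirrors
#' the biological fact that (almost) every chromosome carries at least one
#' RPG, so any monosomy halves the dosage of at least one ribosomal protein;
#' chromosomes listed in `rpgExclude` carry none.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param genesPerChromosome number of genes placed on each chromosome.
#' @param rpgPerChromosome number of RPG-flagged genes per chromosome
#'   (ignored for chromosomes in `rpgExclude`).
#' @param corumFraction probability that a gene is flagged as a CORUM
#'   complex subunit.
#' @param rpgExclude chromosomes carrying no RPG.
#' @param seed integer seed; fixed seed gives an identical annotation.
#' @return A [GenomicRanges::GRanges] sorted by (chromosome, start) with
#'   mcols `gene_id`, `is_rpg`, `is_corum` and seqlengths set. Intervals are
#'   1-based closed internally (BED export converts to 0-based half-open).
#' @examples
#' ann <- simulateAnnotation(c(chrA = 1e6), genesPerChromosome = 10, seed = 1)
#' @export
simulateAnnotation <- function(chromosomes = setNames(rep(60e6, 5), paste0("chr", 1:5)),
                               genesPerChromosome = 200,
                               rpgPerChromosome = 1,
                               corumFraction = 0.3,
                               rpgExclude = character(),
                               seed = NULL) {
  if (length(chromosomes) == 0)
    stop("at least one chromosome is required")
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("chromosomes must be a named vector of lengths")
  if (genesPerChromosome < 1)
    stop("at least one gene per chromosome is required")
  if (rpgPerChromosome < 0) stop("rpgPerChromosome must be >= 0")
  if (corumFraction < 0 || corumFraction > 1)
    stop("corumFraction must be in [0, 1]")
  .with_seed(seed, {
    pieces <- lapply(names(chromosomes), function(chr) {
      len <- chromosomes[[chr]]
      n <- genesPerChromosome
      slot_w <- floor(len / n)
      if (slot_w < 10)
        stop("chromosome ", chr, " too short for ", n, " genes")
      # one gene per equal slot keeps intervals trivially non-overlapping
      max_w <- max(1L, floor(slot_w * 0.5))
      w <- sample.int(max_w, n, replace = TRUE)
      off <- vapply(slot_w - w, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
      start1 <- (seq_len(n) - 1L) * slot_w + off + 1L
      list(chr = rep(chr, n), start = start1, width = w)
    })
    gr <- GRanges(unlist(lapply(pieces, `[[`, "chr")),
                  IRanges(start = unlist(lapply(pieces, `[[`, "start")),
                          width = unlist(lapply(pieces, `[[`, "width"))),
                  seqinfo = Seqinfo(names(chromosomes),
                                    unname(chromosomes)))
    gr <- GenomicRanges::sort(gr)
    n_total <- length(gr)
    gene_id <- sprintf("%s_g%04d", as.character(seqnames(gr)),
                       unlist(lapply(names(chromosomes), function(chr)
                         seq_len(sum(as.character(seqnames(gr)) == chr)))))
    is_rpg <- logical(n_total)
    if (rpgPerChromosome > 0) {
      for (chr in setdiff(names(chromosomes), rpgExclude)) {
        idx <- which(as.character(seqnames(gr)) == chr)
        k <- min(rpgPerChromosome, length(idx))
        is_rpg[sample(idx, k)] <- TRUE
      }
    }
    mcols(gr)$gene_id <- gene_id
    mcols(gr)$is_rpg <- is_rpg
    mcols(gr)$is_corum <- runif(n_total) < corumFraction
    gr
  })
}

#' Simulate binned read-depth coverage
#'
#' Tiles each chromosome into half-open bins and draws a coverage value per
#' bin around `meanDepth * copy / 2`, emulating low-pass whole-genome
#' sequencing of an aneuploid karyotype. Count noise is negative binomial
#' with the given dispersion (variance `mu + dispersion * mu^2`), reducing to
#' Poisson at `dispersion = 0`; `dispersion = NULL` gives noise-free expected
#' coverage.
#'
#' @param annotation a `GRanges` with seqlengths set (e.g. from
#'   [simulateAnnotation()]); only the genome geometry is used.
#' @param karyotype named integer vector chromosome -> copy number
#'   (non-negative); chromosomes absent from it default to 2.
#' @param binSize bin width in bp.
#' @param meanDepth expected coverage of a disomic (copy 2) bin.
#' @param dispersion negative binomial dispersion; 0 = Poisson;
#'   NULL = deterministic.
#' @param seed integer seed.
#' @return A `GRanges` of bins with mcol `coverage`.
#' @export
simulateReadDepth <- function(annotation, karyotype = integer(),
                              binSize = 1e5, meanDepth = 100,
                              dispersion = 0.05, seed = NULL) {
  if (binSize <= 0) stop("binSize must be > 0")
  sl <- seqlengths(annotation)
  if (anyNA(sl)) stop("annotation must carry seqlengths")
  copies <- setNames(rep(2L, length(sl)), names(sl))
  if (length(karyotype)) {
    bad <- setdiff(names(karyotype), names(sl))
    if (length(bad))
      stop("karyotype names not in annotation: ", paste(bad, collapse = ", "))
    if (any(karyotype < 0) || any(karyotype != floor(karyotype)))
      stop("copy numbers must be non-negative integers")
    copies[names(karyotype)] <- as.integer(karyotype)
  }
  bins <- tileGenome(sl, tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
  mu <- meanDepth * copies[as.character(seqnames(bins))] / 2
  cov <- if (is.null(dispersion)) {
    unname(mu)
  } else if (dispersion < 0) {
    stop("dispersion must be >= 0")
  } else {
    .with_seed(seed, {
      if (dispersion == 0) as.numeric(rpois(length(bins), mu))
      else as.numeric(rnbinom(length(bins), mu = mu, size = 1 / dispersion))
    })
  }
  mcols(bins)$coverage <- cov
  bins
}

#' Simulate paired mRNA/protein expression for a monosomic and parental line
#'
#' Draws gene-level log2 intensities for one monosomic line and its diploid
#' parental line, in both modalities, with replicate noise. Each monosomic
#' gene is assigned one of four buffering categories with probabilities
#' `probs`; the category determines the (mRNA, protein) offset applied in the
#' monosomic line: `up;up` -> (muUp, muUp), `down;up` -> (muDown, muUp),
#' `down;down` -> (muDown, muDown), `up;down` -> (muUp, muDown). With
#' `muDown = -1` the un-buffered component sits at the pure 50%-dosage
#' expectation. All genes of the derived line additionally receive a
#' gene-level N(0, sigmaGene) deviation per modality, so disomic fold changes
#' spread around 0.
#'
#' @param annotation `GRanges` from [simulateAnnotation()].
#' @param monosome character vector of monosomic chromosome labels (>= 1).
#' @param probs numeric(4), category probabilities in the order of
#'   [BUFFERING_CATEGORIES]; must sum to 1.
#' @param muDown mean log2FC of an un-buffered ("down") modality (default -1).
#' @param muUp mean log2FC of a buffered ("up") modality (default 0).
#' @param sigmaGene gene-level sd of the log2FC around its category mean.
#' @param sigmaRep additive Gaussian replicate noise sd on the log2 scale.
#' @param nReplicates replicates per line and modality (default 3).
#' @param baseline mean log2 intensity of the parental line.
#' @param baselineSd gene-to-gene sd of baseline intensities.
#' @param corumProteinShift extra protein-level shift added to monosomic
#'   CORUM genes (0 = none); used to emulate complex-driven buffering.
#' @param seed integer seed.
#' @return A list with elements `mrna_sample`, `mrna_parental`,
#'   `protein_sample`, `protein_parental` (each a
#'   [SummarizedExperiment::SummarizedExperiment] with assay `log2`, rowData
#'   carrying gene metadata and a `monosomic` flag) and `truth`
#'   (data.frame `gene_id`, `category` for the monosomic genes).
#' @export
simulateExpression <- function(annotation, monosome,
                               probs = c(0.30, 0.45, 0.20, 0.05),
                               muDown = -1, muUp = 0,
                               sigmaGene = 0.2, sigmaRep = 0.1,
                               nReplicates = 3, baseline = 10,
                               baselineSd = 1, corumProteinShift = 0,
                               seed = NULL) {
  if (length(monosome) == 0)
    stop("monosome chromosome set must not be empty")
  chroms <- as.character(seqnames(annotation))
  if (!all(monosome %in% chroms))
    stop("monosome chromosomes not present in annotation: ",
         paste(setdiff(monosome, chroms), collapse = ", "))
  if (length(probs) != 4 || any(probs < 0) || any(probs > 1) ||
      abs(sum(probs) - 1) > 1e-8)
    stop("probs must be 4 probabilities summing to 1")
  if (sigmaGene < 0 || sigmaRep < 0) stop("sigmas must be >= 0")
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  .with_seed(seed, {
    n <- length(annotation)
    gid <- mcols(annotation)$gene_id
    mono <- chroms %in% monosome
    cat_idx <- integer(n)
    cat_idx[mono] <- sample.int(4, sum(mono), replace = TRUE, prob = probs)
    offsets <- rbind("up;up"     = c(muUp, muUp),
                     "down;up"   = c(muDown, muUp),
                     "down;down" = c(muDown, muDown),
                     "up;down"   = c(muUp, muDown))
    delta <- matrix(0, n, 2, dimnames = list(gid, c("mrna", "protein")))
    delta[mono, ] <- offsets[cat_idx[mono], , drop = FALSE]
    if (corumProteinShift != 0) {
      cm <- mono & mcols(annotation)$is_corum
      delta[cm, "protein"] <- delta[cm, "protein"] + corumProteinShift
    }
    base <- cbind(mrna = rnorm(n, baseline, baselineSd),
                  protein = rnorm(n, baseline, baselineSd))
    # gene-level biological deviation of the derived line, per modality
    gdev <- cbind(mrna = rnorm(n, 0, sigmaGene),
                  protein = rnorm(n, 0, sigmaGene))
    mk <- function(true_level, line) {
      m <- matrix(rnorm(n * nReplicates, mean = true_level, sd = sigmaRep),
                  nrow = n, ncol = nReplicates,
                  dimnames = list(gid, paste0("rep", seq_len(nReplicates))))
      m
    }
    rd <- DataFrame(gene_id = gid, chromosome = chroms,
                    is_rpg = mcols(annotation)$is_rpg,
                    is_corum = mcols(annotation)$is_corum,
                    monosomic = mono)
    se <- function(mat, modality, line) {
      SummarizedExperiment(
        assays = list(log2 = mat), rowData = rd,
        metadata = list(modality = modality, cellLine = line))
    }
    out <- list(
      mrna_sample = se(mk(base[, "mrna"] + delta[, "mrna"] + gdev[, "mrna"]),
                       "mRNA", "monosomic"),
      mrna_parental = se(mk(base[, "mrna"]), "mRNA", "parental"),
      protein_sample = se(mk(base[, "protein"] + delta[, "protein"] +
                               gdev[, "protein"]),
                          "protein", "monosomic"),
      protein_parental = se(mk(base[, "protein"]), "protein", "parental"),
      truth = data.frame(
        gene_id = gid[mono],
        category = factor(BUFFERING_CATEGORIES[cat_idx[mono]],
                          levels = BUFFERING_CATEGORIES),
        stringsAsFactors = FALSE))
    out
  })
}

#' Simulate a polysome profile as a sum of Gaussian peaks
#'
#' The trace is `baseline + sum_k h_k exp(-(x - p_k)^2 / (2 w_k^2)) + noise`
#' over a uniform position grid, emulating the 40S/60S/80S/polysome peaks of
#' a sucrose-gradient UV-absorbance readout. True peak positions and heights
#' are stored in the profile metadata.
#'
#' @param peakPositions strictly increasing peak centers within
#'   `range` (default order 40S, 60S, 80S, polysomes).
#' @param peakHeights,peakWidths per-peak Gaussian height and sd (> 0).
#' @param baseline constant offset.
#' @param noiseSd white-noise sd (0 = noise free).
#' @param nPoints number of samples in the trace.
#' @param range numeric(2) position range of the grid.
#' @param label sample label.
#' @param seed integer seed.
#' @return A [PolysomeProfile-class]; `metadata` holds `true_positions` and
#'   `true_heights`.
#' @export
simulatePolysomeTrace <- function(peakPositions = c(20, 30, 42, 62),
                                  peakHeights = c(0.25, 0.35, 1.0, 0.45),
                                  peakWidths = c(2, 2, 2.5, 7),
                                  baseline = 0.05, noiseSd = 0.01,
                                  nPoints = 1000, range = c(0, 100),
                                  label = "", seed = NULL) {
  k <- length(peakPositions)
  if (length(peakHeights) != k || length(peakWidths) != k)
    stop("peakPositions, peakHeights, peakWidths must be parallel")
  if (any(peakWidths <= 0)) stop("peak widths must be > 0")
  if (k >= 2 && any(diff(peakPositions) <= 0))
    stop("peak positions must be strictly increasing")
  if (any(peakPositions < range[1]) || any(peakPositions > range[2]))
    stop("peak positions must lie within the trace range")
  x <- seq(range[1], range[2], length.out = nPoints)
  y <- rep(baseline, nPoints)
  for (i in seq_len(k))
    y <- y + peakHeights[i] * exp(-(x - peakPositions[i])^2 /
                                    (2 * peakWidths[i]^2))
  if (noiseSd > 0)
    y <- y + .with_seed(seed, rnorm(nPoints, 0, noiseSd))
  polysomeProfile(x, y, label = label,
                  metadata = list(true_positions = peakPositions,
                                  true_heights = peakHeights,
                                  baseline = baseline))
}

#' Simulate a tumor cohort with ploidy strata and TP53-alteration enrichment
#'
#' Samples are assigned to Monosomy/Disomy/Polysomy strata, drawn a ploidy
#' from a stratum-specific normal (truncated at 0.2), a Bernoulli TP53
#' alteration flag, a Beta-distributed TP53 classifier score, a Poisson
#' aneuploidy score and a uniform cancer type. An expression matrix for
#' pathway scoring is generated with `pathwayEffect` subtracted from the
#' member genes of every supplied pathway in Monosomy samples.
#'
#' Defaults emulate the published cohort structure: ploidy strata well
#' separated around the 1.80/2.19 boundaries, TP53 alterations enriched in
#' Monosomy, aneuploidy score comparable in Monosomy and Polysomy but lower
#' in Disomy, and ribosome-like pathways down in Monosomy.
#'
#' @param nSamples number of samples.
#' @param somyFractions numeric(3) (Monosomy, Disomy, Polysomy), sums to 1.
#' @param ploidyMeans,ploidySds numeric(3) per-stratum ploidy distribution.
#' @param tp53AltProb numeric(3) per-stratum alteration probability.
#' @param tp53ScoreShapes 3x2 matrix of Beta shapes per stratum.
#' @param aneuploidyMeans numeric(3) Poisson means of the aneuploidy score.
#' @param nCancerTypes number of cancer types, assigned uniformly.
#' @param nGenes size of the expression gene universe (ids `g0001`, ...).
#' @param pathwayGeneSets named list of gene-id vectors; every member must be
#'   in the universe.
#' @param pathwayEffect log2 shift applied to pathway genes in Monosomy
#'   samples (negative = downregulation).
#' @param seed integer seed.
#' @return A list: `cohort` (data.frame sample, ploidy, somy_truth,
#'   tp53_altered, tp53_score, aneuploidy_score, cancer_type) and
#'   `expression` (genes x samples matrix).
#' @export
simulateCohort <- function(nSamples = 500,
                           somyFractions = c(0.15, 0.70, 0.15),
                           ploidyMeans = c(1.70, 2.00, 2.35),
                           ploidySds = c(0.04, 0.06, 0.05),
                           tp53AltProb = c(0.65, 0.25, 0.35),
                           tp53ScoreShapes = rbind(c(7, 3), c(3, 7), c(4, 6)),
                           aneuploidyMeans = c(12, 4, 12),
                           nCancerTypes = 15,
                           nGenes = 500,
                           pathwayGeneSets = list(),
                           pathwayEffect = -1,
                           seed = NULL) {
  if (length(somyFractions) != 3 || abs(sum(somyFractions) - 1) > 1e-8 ||
      any(somyFractions < 0))
    stop("somyFractions must be 3 non-negative fractions summing to 1")
  if (any(ploidyMeans <= 0)) stop("ploidy means must be positive")
  universe <- sprintf("g%04d", seq_len(nGenes))
  for (nm in names(pathwayGeneSets)) {
    bad <- setdiff(pathwayGeneSets[[nm]], universe)
    if (length(bad))
      stop("pathway '", nm, "' contains genes outside the expression ",
           "universe: ", paste(head(bad, 3), collapse = ", "))
  }
  .with_seed(seed, {
    strata <- c("Monosomy", "Disomy", "Polysomy")
    stratum <- factor(sample(strata, nSamples, replace = TRUE,
                             prob = somyFractions), levels = strata)
    si <- as.integer(stratum)
    ploidy <- pmax(0.2, rnorm(nSamples, ploidyMeans[si], ploidySds[si]))
    altered <- runif(nSamples) < tp53AltProb[si]
    score <- rbeta(nSamples, tp53ScoreShapes[si, 1], tp53ScoreShapes[si, 2])
    aneu <- rpois(nSamples, aneuploidyMeans[si])
    ctype <- sprintf("T%02d", sample.int(nCancerTypes, nSamples,
                                         replace = TRUE))
    expr <- matrix(rnorm(nGenes * nSamples), nrow = nGenes,
                   dimnames = list(universe, sprintf("s%04d",
                                                     seq_len(nSamples))))
    if (length(pathwayGeneSets) && pathwayEffect != 0) {
      mono <- stratum == "Monosomy"
      for (gs in pathwayGeneSets)
        expr[gs, mono] <- expr[gs, mono] + pathwayEffect
    }
    list(cohort = data.frame(sample = colnames(expr), ploidy = ploidy,
                             somy_truth = stratum, tp53_altered = altered,
                             tp53_score = score, aneuploidy_score = aneu,
                             cancer_type = ctype, stringsAsFactors = FALSE),
         expression = expr)
  })
}
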