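## End-to-end orchestration of a fully synthetic run:
## simulate -> copy number -> dosage -> enrichment/ssGSEA -> polysome ->
## cohort, with a manifest of checksums and checksum-based stage skipping.

#' Default pipeline configuration
#'
#' All module parameter blocks with their defaults; pass a modified copy to
#' [runPipeline()]. A single `seed` fans out to deterministic per-stage
#' seeds.
#'
#' @return Named list of parameter blocks.
#' @export
defaultPipelineConfig <- function() {
  list(
    genome = list(chromosomes = setNames(rep(20e6, 5), paste0("chr", 1:5)),
                  genesPerChromosome = 200, rpgPerChromosome = 1,
                  corumFraction = 0.3),
    coverage = list(binSize = 1e5, meanDepth = 100, dispersion = 0.05,
                    monosome = "chr1"),
    expression = list(probs = c(0.30, 0.45, 0.20, 0.05), muDown = -1,
                      muUp = 0, sigmaGene = 0.2, sigmaRep = 0.1,
                      nReplicates = 3),
    buffering = list(cutoff = -0.5),
    enrichment = list(minSize = 10, fdrThreshold = 0.02),
    ssgsea = list(alpha = 0.75, normalize = TRUE),
    polysome = list(window = 57, polyorder = 3,
                    windows = list("40S" = c(12, 26), "60S" = c(26, 36),
                                   "80S" = c(36, 50))),
    cohort = list(nSamples = 500, tMono = 1.80, tPoly = 2.19, alpha = 0.05)
  )
}

.stage_seed <- function(seed, k) (as.integer(seed) + 7919L * k) %% 2147483629L

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(md5sum(f))
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic genome, coverage, paired expression, polysome traces
#' and a cohort; then runs copy-number calling, normalization + fold changes
#' + buffering classification, 2D enrichment, ssGSEA group comparison,
#' polysome quantification and cohort stratification. All stage outputs are
#' written as plain-text files under `outDir` together with `manifest.json`
#' (config hash, seed, package version, per-file md5 checksums) and
#' `summary.json`. When a manifest from a previous run with the same config
#' hash and seed is found and a stage's recorded outputs still match their
#' checksums, that stage is skipped.
#'
#' @param outDir output directory (created if missing).
#' @param seed global integer seed.
#' @param config configuration list, see [defaultPipelineConfig()].
#' @param force rerun all stages even when outputs are up to date.
#' @return Invisibly, the manifest list; `summary.json` holds somy calls,
#'   buffering fractions and medians, enrichment hits, ssGSEA p-value,
#'   polysome peak ratios and cohort enrichment results.
#' @export
runPipeline <- function(outDir, seed = 1, config = defaultPipelineConfig(),
                        force = FALSE) {
  stopifnot(is.list(config))
  req <- names(defaultPipelineConfig())
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("config is missing blocks: ", paste(miss, collapse = ", "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  chash <- .config_hash(config)
  manifest_path <- file.path(outDir, "manifest.json")
  prev <- NULL
  if (!force && file.exists(manifest_path)) {
    prev <- tryCatch(read_json(manifest_path, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) &&
        (!identical(prev$config_hash, chash) ||
         !identical(as.integer(prev$seed), as.integer(seed))))
      prev <- NULL
  }
  stage_current <- function(files) {
    !is.null(prev) && all(files %in% names(prev$checksums)) &&
      all(file.exists(file.path(outDir, files))) &&
      identical(unname(md5sum(file.path(outDir, files))),
                unname(unlist(prev$checksums[files])))
  }
  outfiles <- character()
  note <- function(...) outfiles <<- union(outfiles, c(...))

  ## --- simulate ---------------------------------------------------------
  g <- config$genome
  ann <- simulateAnnotation(chromosomes = g$chromosomes,
                            genesPerChromosome = g$genesPerChromosome,
                            rpgPerChromosome = g$rpgPerChromosome,
                            corumFraction = g$corumFraction,
                            seed = .stage_seed(seed, 1L))
  sim_files <- c("genes.bed", "bins.bedgraph", "mrna_sample.tsv",
                 "mrna_parental.tsv", "protein_sample.tsv",
                 "protein_parental.tsv", "truth_categories.tsv",
                 "trace_sample.csv", "trace_reference.csv", "cohort.tsv",
                 "cohort_expression.tsv", "terms.gmt")
  cv <- config$coverage; ex <- config$expression; co <- config$cohort
  karyotype <- setNames(rep(1L, length(cv$monosome)), cv$monosome)
  if (force || !stage_current(sim_files)) {
    writeGeneAnnotation(ann, file.path(outDir, "genes.bed"))
    bins <- simulateReadDepth(ann, karyotype = karyotype,
                              binSize = cv$binSize, meanDepth = cv$meanDepth,
                              dispersion = cv$dispersion,
                              seed = .stage_seed(seed, 2L))
    writeBinnedCoverage(bins, file.path(outDir, "bins.bedgraph"))
    sim <- simulateExpression(ann, monosome = cv$monosome, probs = ex$probs,
                              muDown = ex$muDown, muUp = ex$muUp,
                              sigmaGene = ex$sigmaGene,
                              sigmaRep = ex$sigmaRep,
                              nReplicates = ex$nReplicates,
                              seed = .stage_seed(seed, 3L))
    for (nm in c("mrna_sample", "mrna_parental", "protein_sample",
                 "protein_parental"))
      writeExpressionMatrix(sim[[nm]], file.path(outDir, paste0(nm, ".tsv")))
    write.table(sim$truth, file.path(outDir, "truth_categories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tr_s <- simulatePolysomeTrace(peakHeights = c(0.30, 0.45, 1.0, 0.5),
                                  label = "monosomic",
                                  seed = .stage_seed(seed, 4L))
    tr_r <- simulatePolysomeTrace(peakHeights = c(0.25, 0.35, 1.2, 0.45),
                                  label = "parental",
                                  seed = .stage_seed(seed, 5L))
    writeTrace(tr_s, file.path(outDir, "trace_sample.csv"))
    writeTrace(tr_r, file.path(outDir, "trace_reference.csv"))
    ribosome_like <- sprintf("g%04d", 1:30)
    coh <- simulateCohort(nSamples = co$nSamples,
                          pathwayGeneSets = list(ribosome = ribosome_like),
                          seed = .stage_seed(seed, 6L))
    writeCohortTable(coh$cohort, file.path(outDir, "cohort.tsv"))
    writeExpressionMatrix(coh$expression,
                          file.path(outDir, "cohort_expression.tsv"))
    chroms <- as.character(seqnames(ann))
    gid <- mcols(ann)$gene_id
    terms <- split(gid, chroms)
    terms$CORUM <- gid[mcols(ann)$is_corum]
    set.seed(.stage_seed(seed, 7L))
    for (k in 1:10)
      terms[[sprintf("GO_like_%02d", k)]] <-
        sample(gid, sample(15:60, 1))
    writeGmt(terms, file.path(outDir, "terms.gmt"))
  }
  note(sim_files)

  ## --- copy number ------------------------------------------------------
  bins <- readBinnedCoverage(file.path(outDir, "bins.bedgraph"))
  gc <- geneCoverageTable(bins, ann)
  somy <- callSomy(gc)
  write.table(gc, file.path(outDir, "gene_coverage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(somy, file.path(outDir, "somy_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("gene_coverage.tsv", "somy_calls.tsv")

  ## --- dosage -----------------------------------------------------------
  sim <- list(
    mrna_sample = .se_from_file(file.path(outDir, "mrna_sample.tsv"), ann),
    mrna_parental = .se_from_file(file.path(outDir, "mrna_parental.tsv"), ann),
    protein_sample = .se_from_file(file.path(outDir, "protein_sample.tsv"),
                                   ann),
    protein_parental = .se_from_file(file.path(outDir,
                                               "protein_parental.tsv"), ann))
  rd <- rowData(sim$mrna_sample)
  rd$monosomic <- rd$chromosome %in% cv$monosome
  for (nm in names(sim)) SummarizedExperiment::rowData(sim[[nm]]) <- rd
  fct <- buildFoldChangeTable(sim, monosome = cv$monosome)
  writeFoldChangeTable(fct, file.path(outDir, "fold_changes.tsv"))
  buff <- classifyBuffering(fct, cutoff = config$buffering$cutoff)
  note("fold_changes.tsv")

  ## --- enrichment -------------------------------------------------------
  terms <- readGmt(file.path(outDir, "terms.gmt"))
  m <- matchedGenes(fct)
  xv <- setNames(m$mrna_log2fc, m$gene)
  yv <- setNames(m$protein_log2fc, m$gene)
  enr <- enrichment2D(xv, yv, terms, minSize = config$enrichment$minSize,
                      fdrThreshold = config$enrichment$fdrThreshold,
                      filter = FALSE)
  write.table(enr, file.path(outDir, "enrichment2d.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("enrichment2d.tsv")

  ## --- ssGSEA + cohort --------------------------------------------------
  cohort <- readCohortTable(file.path(outDir, "cohort.tsv"))
  cexpr <- readExpressionMatrix(file.path(outDir, "cohort_expression.tsv"))
  scores <- scoreMatrix(cexpr, list(ribosome = sprintf("g%04d", 1:30)),
                        alpha = config$ssgsea$alpha,
                        normalize = config$ssgsea$normalize)
  cohort$somy <- classifySomy(cohort$ploidy, co$tMono, co$tPoly)
  md <- cohort$somy %in% c("Monosomy", "Disomy")
  ssg_p <- compareGroups(scores[md, "ribosome"],
                         droplevels(cohort$somy[md]),
                         alternative = "less")$p_value
  enrich <- tp53Enrichment(cohort$somy, cohort$tp53_altered,
                           comparison = "disomy")
  per_type <- perTypeScoreComparison(cohort, scoreColumn = "tp53_score",
                                     alpha = co$alpha)
  write.table(per_type$per_type, file.path(outDir, "per_type_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("per_type_tests.tsv")

  ## --- polysome ---------------------------------------------------------
  ps <- config$polysome
  tr_s <- smoothProfile(readTrace(file.path(outDir, "trace_sample.csv"),
                                  "monosomic"), ps$window, ps$polyorder)
  tr_r <- smoothProfile(readTrace(file.path(outDir, "trace_reference.csv"),
                                  "parental"), ps$window, ps$polyorder)
  tr_s <- scaleToReference(tr_s, tr_r, ps$windows)
  peaks <- locateSubunitPeaks(tr_s, ps$windows)
  ratios <- subunitRatios(peaks)

  ## --- summary + manifest ----------------------------------------------
  summary <- list(
    somy_calls = somy,
    buffering = list(fractions = as.list(categoryFractions(buff)),
                     medians = foldChangeMedians(buff)),
    enrichment_hits = enr$term[enr$fdr < config$enrichment$fdrThreshold],
    ssgsea_monosomy_vs_disomy_p = ssg_p,
    tp53_enrichment = list(odds_ratio = enrich$odds_ratio,
                           p_value = enrich$p_value),
    per_type_significant = as.list(per_type$n_significant),
    polysome_ratios = as.list(ratios))
  write_json(summary, file.path(outDir, "summary.json"), auto_unbox = TRUE,
             digits = NA, force = TRUE)
  note("summary.json")
  sums <- md5sum(file.path(outDir, outfiles))
  names(sums) <- outfiles
  manifest <- list(config_hash = chash, seed = as.integer(seed),
                   package_version = as.character(utils::packageVersion(
                     "monosomics")),
                   checksums = as.list(sums))
  write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# rebuild a SummarizedExperiment from a TSV matrix + annotation
.se_from_file <- function(path, annotation) {
  m <- readExpressionMatrix(path)
  idx <- match(rownames(m), mcols(annotation)$gene_id)
  if (anyNA(idx)) stop("matrix genes not found in annotation: ", path)
  rd <- DataFrame(gene_id = rownames(m),
                  chromosome = as.character(seqnames(annotation))[idx],
                  is_rpg = mcols(annotation)$is_rpg[idx],
                  is_corum = mcols(annotation)$is_corum[idx],
                  monosomic = FALSE)
  SummarizedExperiment(assays = list(log2 = m), rowData = rd)
}
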