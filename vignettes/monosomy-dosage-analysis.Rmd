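---
title: "Quantifying dosage compensation and its consequences in monosomic cells"
author: "monosomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dosage compensation and its consequences in monosomic cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monosomics)
```

# The scientific problem

Losing one copy of a chromosome halves the DNA template of every gene on it.
If transcription and translation simply tracked template number, every
monosomic gene would be expressed at 50% of the diploid level -- a log2 fold
change (log2FC) of exactly -1 against the isogenic parental line. Measured
monosomic cells do not behave this way: transcript medians land well above
-1, and protein medians land above the transcript medians, implying both
transcriptional and posttranscriptional buffering. Quantifying that
buffering, and its downstream consequences (ribosome biogenesis defects when
a ribosomal protein gene is haploid; selection against functional p53 in
monosomic tumors), requires a chain of analyses that this package implements
as a tested, reusable pipeline operating entirely on plain-text inputs.

A synthetic-data module generates every input with known ground truth, so
each stage can be validated as a parameter-recovery problem without any
external download.

# Copy-number calling from binned coverage

Low-pass whole-genome sequencing is summarized as binned coverage (BED-like
half-open intervals). The calling chain is deliberately simple:

1. **Bin-to-gene assignment** (`assignBinsToGenes()`): a bin belongs to a
   gene iff the half-open intervals overlap by at least 1 bp; a straddling
   bin counts for both genes. Genes without any mapped bin are dropped.
2. **Per-gene summary** (`perGeneLog2Median()`): the median of
   `log2(coverage + pseudocount)` over the gene's bins. The pseudocount
   (default 1) keeps zero-coverage bins finite; the per-gene median over
   bins is our reading of the ambiguous "median coverage per read" phrasing
   that sequencing pipelines in this area use.
3. **Centering** (`centerCoverage()`): subtracting the cell-line-wide median
   puts the disomic bulk at 0, so a chromosome present at one copy centers
   near `log2(1/2) = -1`. Centering is idempotent and removes global
   sequencing depth, so somy calls are depth invariant.
4. **Calling** (`callSomy()`): a chromosome's median centered value is
   compared against a loss cutoff of -0.5 (the midpoint between the copy-1
   expectation of -1 and the copy-2 expectation of 0) and a gain cutoff of
   +0.42; chromosomes with fewer than 20 measured genes are reported
   `uncallable` rather than guessed. Note the gain cutoff is deliberately
   conservative -- it sits between the arithmetic midpoint (+0.29) and the
   full copy-3 expectation `log2(3/2) = +0.585`; both cutoffs are arguments.

One caveat is visible in simulations: with a large fraction of the genome
monosomic, the global median centering shifts the disomic bulk slightly
above zero (the global median is a quantile of a mixture). At the 20% level
used in our tests the disomic offset is ~0.1 log2 units, far from either
cutoff. Arm-level events are supported by annotating an arm as its own
"chromosome" label; there is no automatic segmentation (no CBS/HMM), and no
GC correction (inputs are assumed GC-normalized upstream).

# Normalization and fold changes

Replicate log2 intensity matrices (mRNA and protein, typically 3 replicates)
are normalized by **median shift excluding the monosomic genes**
(`medianShiftNormalize()`): each replicate is shifted additively so its
median over non-excluded genes equals the grand median of those medians.
Excluding the monosomic genes is essential -- the lost chromosome lowers the
whole sample's intensity distribution, and normalizing on all genes would
partially erase the very signal being measured. The same per-replicate shift
is applied to the excluded genes. Fold changes (`log2FoldChange()`) are the
difference of per-gene replicate medians, sample minus parental.

# Buffering classification

On the matched set (genes quantified in both modalities),
`classifyBuffering()` assigns each monosomic gene to one of four categories
at a cutoff of -0.5 (halfway between no change and full dosage loss):

| category    | mRNA      | protein   | interpretation                    |
|-------------|-----------|-----------|-----------------------------------|
| `up;up`     | > -0.5    | > -0.5    | buffered transcriptionally        |
| `down;up`   | <= -0.5   | > -0.5    | buffered posttranscriptionally    |
| `down;down` | <= -0.5   | <= -0.5   | not buffered                      |
| `up;down`   | > -0.5    | <= -0.5   | protein-specific loss (rare)      |

The published category definitions use strict inequalities on both sides and
leave exact equality unassigned; we assign the boundary to the "down" side,
which is conservative for buffering claims (it never inflates the buffered
fractions). The cutoff is an argument. `pooledMonosomeMedians()` pools
matched monosomic gene records across cell lines (record-level: a gene
monosomic in two lines counts twice) excluding chromosome X, where
X-inactivation already silences one copy. `complexMembershipShift()`
contrasts CORUM complex subunits with other proteins, reporting medians plus
histogram counts on a fixed grid (width 0.1 over [-3, 3]) rather than kernel
densities, so summaries are exactly reproducible. `sharedExtremeProteins()`
lists proteins beyond |log2FC| > 1.5 in at least two lines, requiring a
shared direction.

# Rank-based 2D annotation enrichment

`enrichment2D()` scores each annotation term in two dimensions (mRNA and
protein fold change) as

\[ s = \frac{2\,(\overline{r}_{\text{members}} -
\overline{r}_{\text{non-members}})}{n} \in [-1, 1], \]

where \(r\) are average ranks over the matched universe. A term occupying
the top \(m\) ranks of a dimension scores exactly +1 there. Significance is
a per-dimension two-sided Mann-Whitney test combined per term as
\(\min(1, 2\min(p_x, p_y))\) (Bonferroni over the two dimensions), with
Benjamini-Hochberg FDR across terms and a default reporting threshold of
FDR < 0.02. The Mann-Whitney combination is an approximation of the original
multivariate 2D test statistic; scores are unaffected by this choice. Terms are intersected
with the measured universe before the minimum-size filter (default 10,
configurable).

# ssGSEA pathway scores

`ssgseaScore()` implements the single-sample GSEA statistic in its
sum-based form: genes are ranked by expression (descending; ties broken by
gene id so results are reproducible), and the score is the summed difference
between the weighted in-set ECDF and the uniform out-of-set ECDF, with
in-set weights `|rank|^alpha` normalized to 1. The canonical exponent
`alpha = 0.75` is the default; at `alpha = 0` the statistic depends only on
gene order and is invariant under monotone transforms of expression.
`scoreMatrix()` optionally divides each set's scores by their across-sample
range. Group comparisons use one-sided Wilcoxon rank-sum tests
(`compareGroups()`), exact by enumeration when both groups have at most 12
samples and no ties, and the normal approximation with continuity correction
otherwise. No permutation-based NES/FDR machinery is provided -- group
inference is rank-sum only.

# Polysome profiles

Sucrose-gradient UV traces are smoothed with a Savitzky-Golay filter
(`smoothProfile()`; window 57 points by default -- the midpoint of the
conventional 51-61 range -- cubic polynomial). The filter is exact on
polynomials up to its order, which the tests exploit as an oracle. Unevenly
sampled traces are linearly resampled to a uniform grid first. Peak
localization (`locateSubunitPeaks()`) is the windowed global maximum of the
smoothed trace per species, with user-supplied 40S/60S/80S windows (no
automatic sedimentation calibration); a species whose window maximum does
not exceed baseline + 1% of the dynamic range is "not detected".
`scaleToReference()` multiplies a profile by `reference 80S height / sample
80S height` so its 80S peak matches the reference. The literal published
phrasing multiplies by the reciprocal, which would not equalize the peaks;
because the figures state profiles were adjusted *to* the 80S peak, the
equalizing direction is the default and `invert = TRUE` restores the literal
one. `subunitRatios()` reports 60S/40S, 80S/40S and 80S/60S peak-height
ratios, optionally baseline-subtracted; all ratios are invariant to scaling
the raw trace.

# Cohort stratification

`classifySomy()` cuts ploidy at `tMono = 1.80` and `tPoly = 2.19`
(equality to Disomy, so ploidy 2.0 is always disomic). The published stratum
ranges overlap (1.66-1.90 for the monosomy boundary, 2.0-2.27 for the
polysomy boundary); we read them as *sweep ranges* for the two boundaries
and take the point defaults from the disomic-range sentence.
`thresholdSweep()` re-tests TP53 enrichment over the full boundary grid and
flags the result robust only when significant everywhere.
`tp53Enrichment()` uses a one-sided Fisher's exact test (the source does not
name a test; Fisher is the natural exact choice for a 2x2) and reports the
sample odds ratio with a Haldane correction on zero cells. Monosomy vs
Disomy is the default comparison, Monosomy vs rest is available.
`perTypeScoreComparison()` runs one-sided rank-sum tests per cancer type
with a minimum group size of 3 and no cross-type correction by default
(a BH option exists); `aneuploidyConfoundSummary()` checks the
SCNA-burden confound: comparable aneuploidy scores in Monosomy and Polysomy
alongside TP53 alterations enriched only in Monosomy.

# What the generators emulate -- and what they do not

* `simulateReadDepth()` draws negative binomial counts around
  `meanDepth * copy / 2` (variance `mu + dispersion * mu^2`; Poisson at
  dispersion 0, deterministic when dispersion is `NULL`). Real coverage has
  GC waves and mappability structure that are *not* modeled; the generator
  validates the normalization/calling logic, not artifact removal.
* `simulateExpression()` draws each monosomic gene's category from the
  four-component mixture, then applies the category's (mRNA, protein) offset
  (`muDown = -1` for un-buffered, `muUp = 0` for buffered) plus gene-level
  N(0, `sigmaGene`) and replicate N(0, `sigmaRep`) Gaussian noise on the
  log2 scale. The default mixture (0.30, 0.45, 0.20, 0.05) mirrors the
  published fractions. No noise model is published, so `sigmaGene = 0.2`
  and `sigmaRep = 0.1` were chosen once as values typical of replicated
  bulk omics; they are tunable and not estimated from deposited data.
  Modality noise is independent per gene, so mRNA-protein correlation beyond
  the category structure is not emulated, and there are no missing protein
  values (real TMT data has them; the matched-set logic is still exercised
  via the table contract).
* `simulatePolysomeTrace()` sums Gaussian peaks on a constant baseline with
  white noise; real traces have drifting baselines and asymmetric peaks.
* `simulateCohort()` draws ploidy strata around well-separated means
  (1.70/2.00/2.35, sd 0.04-0.06), Bernoulli TP53 alterations per stratum
  (defaults 0.65/0.25/0.35), Beta classifier scores, Poisson aneuploidy
  scores (equal means 12 in Monosomy and Polysomy, 4 in Disomy by design),
  and uniform cancer types (15 by default, matching the pan-cancer figure).
  Real ploidy distributions are continuous without clean minima -- that is
  precisely why the threshold sweep exists -- so classification accuracy on
  synthetic cohorts (>= 99%) is an upper bound, not a field estimate.

Consequently, passing tests demonstrate that the *computational contract* of
each stage is correct and that parameters are recovered under the stated
noise model; they do not certify performance on data with structured
artifacts the generators omit.

# Numerical choices and degenerate inputs

* Buffering cutoff equality goes to "down" (see above); all cutoffs are in
  (-1, 0) by validity.
* Zero-coverage bins: pseudocount 1 by default.
* Expression ranking ties: broken by gene id, so ssGSEA is deterministic.
* Wilcoxon: exact only without ties and both groups <= 12; otherwise normal
  approximation with continuity correction.
* Fisher odds ratio: sample OR, Haldane 0.5 on zero cells (the p-value is
  always from the exact conditional test).
* Flat polysome traces yield "not detected" species rather than spurious
  peaks; undetected species make ratios an error, not NA arithmetic.
* Empty exclusion complements, empty monosome sets, all-CORUM or no-CORUM
  tables, single-class cohorts: all are explicit errors with messages naming
  the offending input.
* The pipeline seed fans out to per-stage seeds as `seed + 7919 * stage`
  (kept below 2^31), so stages are individually reproducible.

# Problem sizes used by the test suite

The suite validates statistical behavior at sizes chosen to make Monte
Carlo assertions sharp while staying desk-scale: 1000 monosomic genes for
the pure-dosage null (the median's sampling sd is ~0.008, an order of
magnitude under the +/-0.05 tolerance); 50 seeds x 300 monosomic genes (the
scale of a typical human autosome's matched genes) for mixture-fraction
recovery; 2000 null cohorts of 5722 samples (the pan-cancer cohort size
after WGD filtering) for Fisher calibration; and exhaustive enumeration for
every rank-sum instance up to 8 per group and Fisher table up to n = 20.

# Known limitations

* The 2D enrichment p-value is a Bonferroni combination of per-dimension
  Mann-Whitney tests, not the original multivariate statistic; scores match
  the published definition exactly.
* Within-proteome 2D comparisons (one monosomy vs another) use the same
  machinery and FDR threshold; whether the original analysis did is not
  documented, so it is configurable.
* No imputation, no TMT ratio-compression correction, no differential
  expression models: the pipeline consumes post-processed log2 intensities.
* Cohort functions consume ploidy, TP53 classifier scores and aneuploidy
  scores as inputs; none of the upstream inference (ABSOLUTE, classifier
  training, WGD calling) is re-implemented.
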