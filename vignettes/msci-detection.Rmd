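---
title: "Detecting meiotic X silencing from stage-enriched transcriptomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting meiotic X silencing from stage-enriched transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msciseq)
```

`msciseq` detects meiotic sex chromosome inactivation (MSCI) from
stage-enriched spermatogenesis expression data. This vignette documents the
statistical models, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices a
maintainer should know about. Every empirical rate quoted here is computed
by the package's own test suite or by `scripts/acceptance.R`; nothing is
imported from elsewhere.

## The data and its two core difficulties

The input is a gene × sample matrix of counts (plus TPM or gene lengths)
from dissected testis regions enriched for mitosis, meiosis and
post-meiosis, with replicates, together with a gene annotation carrying
chromosome class (X, neo-X, autosome, dot, Y — assigned from Muller
elements, which are conserved across Drosophila), biotype, and a gene-age
branch (0 = old, predating the subgenus split; 1–6 = progressively
younger).

Two features of such data shape everything downstream:

1. **Stage impurity.** Dissected regions are enriched, not pure. A
   nominally meiotic sample is a mixture of neighbouring stages, which
   dilutes every meiotic effect toward the mitotic/post-meiotic state.
2. **Expression-distribution asymmetry.** The X carries relatively fewer
   lowly expressed genes in testis than the autosomes, so a ratio of plain
   medians overstates X expression. Estimators must compare like with
   like.

## Differential expression: a transparent NB Wald pipeline

Counts for gene *g* in sample *j* are modelled as negative binomial with
mean μ and dispersion α (Var = μ + αμ²; α = 0 recovers Poisson, the
dominant RNA-seq convention).

* **Normalization** — median-of-ratios size factors: genes with a zero in
  any sample are dropped; each remaining gene's counts are divided by its
  geometric mean across samples; a sample's factor is the median of those
  ratios. This matches the standard reference implementation up to the
  even-*n* median midpoint convention (the reference takes the median on
  the log scale; agreement is ~1e-5 relative).
* **Dispersion** — per gene, a method-of-moments estimate on normalized
  counts pooled within replicate groups: α̂ = max(α_floor, (s² − m̄)/m̄²),
  combined across groups by a df-weighted mean, with α_floor = 1e-8. No
  shrinkage is applied; this keeps the estimator simple and analyzable, at
  the cost of noisy per-gene dispersions at 3 replicates. Its calibration
  is therefore demonstrated empirically (below) rather than assumed.
* **Wald test** — per gene, the two-group GLM
  log μ = log s_j + β₀ + β₁·x_j (x = 1 in the numerator stage) is fit by
  Fisher-scoring IRLS at fixed α̂, vectorized across all genes (each
  iteration solves the per-gene 2×2 weighted least-squares system in
  closed form). The standard error of β₁ comes from the observed
  information at the MLE; log2FC = β₁/ln 2; two-sided normal p-value.
  Coefficients are clamped at ±50 on the natural-log scale and IRLS runs
  to a 1e-8 coefficient tolerance with a 100-iteration cap;
  non-convergent genes get missing p-values.
* **Filtering and classes** — genes with mean normalized count < 1 across
  the contrast's samples are `untested` (independent filter). BH
  adjustment runs over tested genes only; `down`/`up` means q < 0.05 with
  the corresponding sign. The 0.05 default is a choice — no threshold is
  canonical for this classification — and is a single argument away.

The suite checks the fit against two independent routes: a direct
Nelder–Mead maximization of the NB likelihood with a finite-difference
Hessian (agreement to 3 decimals on fixtures), and a fixed-theta NB GLM
from a standard package (log2FC agreement to 1e-4 on simulated genes).

**Calibration, measured.** On 500 simulated global-null datasets (5,000
genes, 3 replicates/stage), per-dataset Wald p-values are near-uniform
(median Kolmogorov–Smirnov distance ≈ 0.039; the suite requires < 0.1) and
the genome-wide fraction of q < 0.05 calls stays within the FDR target.
The moment estimator's small-sample noise makes extreme tails slightly
anti-conservative — a handful of false positives per 5,000 genes — which
is why enrichment, not per-gene significance, carries the MSCI conclusion.

**Power, measured.** With three replicates, dispersion 0.05 and a
four-fold reduction, detection power is ≈ 0.75 overall under the
generator's realistic baseline-expression spread, and > 0.9 for genes with
mean normalized count ≥ 30; both match an analytic normal-approximation
power oracle. Per-gene power is *not* the point: aggregated over hundreds
of X genes, the enrichment flag is raised in ≥ 99% of simulated MSCI
datasets (half the X silenced two-fold) even under 70% stage purity.

## Enrichment by chromosome class

Proportions of down/up genes use **all annotated genes of the biotype** in
each class as denominators (not only tested genes), so classes with
different detection rates remain comparable; both counts are reported.
Each non-autosomal class is tested against autosomes with the
Yates-corrected chi-square (χ² = Σ (max(|O−E| − ½, 0))²/E, 1 df), with
significance stars at p ≤ 0.05/0.01/0.001. Two deliberate consequences:

* The continuity correction makes the test conservative at small counts.
  Under global-null simulation the X-down flag fires in ~2% of datasets at
  nominal 5% — type-I error is controlled, but under-rejection is the
  price of this classical test choice.
* The dot chromosome (Muller F) has an order of magnitude fewer genes than
  other classes; its tests are emitted with a `low_power` flag when the
  class has < 100 annotated genes.

If a direction has no regulated genes anywhere (common under the null),
the 2×2 table has a zero margin; the test is reported as χ² = 0, p = 1
(no evidence) rather than an error.

`positional_profile()` summarizes where regulated genes sit along a
chromosome (binned midpoints) and attaches a one-sample KS statistic
against uniformity. The KS choice is this package's operationalization of
"uniformly distributed along the chromosome" — the underlying comparison
is descriptive in origin — and is labelled as such in the output.

## X:AA estimators

`xaa_filter_by_fraction()` implements the matched-fraction estimator: at
threshold t (strict `>`, with t ∈ {0, 2, 10} TPM as defaults), compute
each class's fraction of genes above t, take the minimum f across X,
(neo-X,) autosomes, select each class's top k = ⌊f·n + 1e-9⌋ genes
(k ≥ 1; the epsilon keeps exact multiples of 1/n intact in floating
point; boundary ties break by stable gene-id order), and report
median(top X)/median(top A). The minimizing class recovers exactly its
above-threshold set. With neo-X present the common three-way minimum
fraction is used and both X:AA and NeoX:AA are returned.
`xaa_by_expression()` is the plain thresholded median ratio for
comparison. An exhaustive small-grid equivalence against an independently
coded brute-force implementation (all class sizes ≤ 8, integer TPMs ≤ 12)
is part of the acceptance suite.

Ratios are computed per replicate (that sample's TPM) and pooled (mean
TPM across a stage's replicates); the published boxplots' sampling unit is
not stated, so both scopes are emitted and the stage comparison
(Wilcoxon rank-sum, exact for ≤ 10 per group without ties) uses the
per-replicate values.

A useful analytic fact, exploited by the recovery tests: under **pure**
stages, uniform silencing of all X genes by log2FC −1 exactly halves the
meiotic X:AA at t = 0 (TPM renormalization cancels in the ratio of
medians). Stage mixing attenuates this toward 1 — with the default 70%
purity, expected meiotic X:AA under half-silencing is 0.83 versus 1.01
mitotic (the simulation recovers 0.831/1.013). The halving check therefore
runs with identity purity; that is the configured condition, not a
convenience.

## Gene-age trajectories

Per-gene stage values average replicates of log₂(normalized count + 1)
— genes, not samples, are the sampling unit of the downstream tests,
consistent with the very large degrees of freedom such contrasts show.
The pseudocount (default 1) is required by zeros and is configurable, as
is the expression unit (size-factor-normalized counts by default, TPM
optionally). Cell means ± SEM are reported per (age group × chromosome
class × stage); empty cells (e.g. no new dot genes) are absent, not
imputed. Contrasts are two-sided rank-sum tests: new-X vs old-X and
new-X vs new-autosome at every stage, plus old-X mitosis vs meiosis.

## Profiles and QC

Stage profiles are Z-scored per gene with the population (n-denominator)
standard deviation — with three stages the sample sd would discard a third
of the information; either convention is defensible, this one is fixed and
documented. Zero-variance genes are excluded and reported. Clustering
uses `stats::kmeans` (Hartigan–Wong) with 50 random restarts under a
mandatory seed; k defaults to 12, the number of spermatogenic profile
classes established for these transcriptomes. A k-means++ initialization
was considered and rejected: the standard implementation with many
restarts attains the exhaustively verified optimum on small instances
(the suite enumerates all 2-partitions of 7 points), and reusing the
stock implementation is preferable to a bespoke initializer. Whether
clusters should be fit jointly across datasets or per dataset and matched
is left to the user; the default is per dataset.

QC helpers compute log₂ Pearson correlations between samples and a
sample-level PCA of log₂ expression (centered per gene). In simulations
where a shared stage program dominates mild species-specific shifts,
stages separate along PC1 ahead of species — the qualitative pattern
expected of conserved spermatogenesis programs. Note that a stage program
shared identically by *all* genes is invisible after within-sample TPM
normalization; stage separation requires differential programs, which is
also true of real data.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; `simulate_experiment()`
draws from them deterministically given the seed (bit-identical reruns).
The generative model:

* per-gene baseline log₂ mean ~ N(5, 2) (about 32 normalized counts at
  the median, spanning near-silent to highly expressed), dispersion 0.1
  (constant by default, optionally log-normal per gene);
* chromosome classes sized like a Drosophila genome: 750 X (~15%),
  4,100 autosomal, 30 dot (~0.6%), 20 Y, in 3 stages × 3 replicates;
* MSCI: a fraction (default 0.5) of X/neo-X genes shifted by
  msci_log2fc (default −1) in meiosis only;
* age programs (defaults): new X genes +1 log₂ at all stages; new
  autosomal genes 0/+0.5/+1 across stages, converging with new X genes
  post-meiotically; old genes flat; 10% of genes are new;
* library sizes log-normal (sd 0.2 on the log scale); gene lengths
  log-normal (median 2 kb) used only for TPM — counts are
  length-independent by design, which keeps expectations closed-form;
* stage impurity: expected means are blended through a row-stochastic
  purity matrix (default 70% target stage, 15% each neighbour). Mixing
  happens on expectations, not by sampling cell labels: sufficient for
  bulk-level structure and again closed-form. The published work gives no
  impurity estimate, so the default is illustrative; every analysis here
  is exercised at both 70% and identity purity.

`analytic_expectations()` returns the implied per-stratum means (pre- and
post-mixture) and the population X:AA ratio per stage (the class medians
solve a mixture-of-lognormals quantile equation). These are the targets of
the moment-matching, mean-recovery and ratio-recovery tests, including a
brute-force 10⁶-draw sampling check.

What the generator does **not** emulate: read-level noise, gene length ×
count coupling, isoforms, correlated genes, batch structure, and
single-cell heterogeneity. Passing recovery tests therefore shows the
estimators do what they claim under the stated generative assumptions —
it does not certify performance on real data with those extra features.

Null-calibration runs use `null_simulation_config()`: MSCI off **and** all
age-specific stage programs off, since any class × stage interaction
(including the age defaults) breaks the global null that calibration
requires; impurity and library-size variation are retained because they
do not.

## Problem sizes and runtime

The acceptance suite simulates 500 global-null datasets and 200 MSCI
datasets at 4,900–5,000 genes × 9 samples, 100 age-dynamics datasets at
800 genes, and one 19,200-gene dataset for the halving check; the
vectorized IRLS makes a full simulate–test–enrich pass ~0.15 s, so the
whole suite runs in a few minutes on one CPU. These sizes give Monte
Carlo error comfortably below the margins being asserted (binomial SE
≤ 2.2 percentage points on rate checks).

## Known limitations

* Moment dispersions without shrinkage are noisy at 3 replicates; the
  pipeline compensates by aggregating evidence across genes, and per-gene
  q-values should be read accordingly.
* The Yates-corrected enrichment test under-rejects at small regulated
  counts (measured ~2% at nominal 5% under the null).
* "Paired" replicate designs are not modelled: contrasts treat replicates
  as independent pools, which matches dissection-pool replicates but not
  genuinely paired designs.
* The E–F fusion junction side (which side of the junction is dot) is a
  configuration choice (`dot_side`, default `"below"`): the published
  mapping identifies the junction interval but not the orientation
  unambiguously.
* X:AA ratios cannot by themselves distinguish MSCI from a meiotic loss
  of dosage compensation; that interpretive question is outside this
  package's scope.
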