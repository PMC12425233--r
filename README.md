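# msciseq

Detecting **meiotic sex chromosome inactivation (MSCI)** from stage-enriched
spermatogenesis RNA-seq.

During male meiosis in many animals, the X chromosome is transcriptionally
silenced. In bulk RNA-seq of dissected testis regions enriched for mitotic,
meiotic and post-meiotic germ cells, MSCI shows up as (i) an excess of
X-linked genes downregulated in meiosis relative to mitosis, and (ii) a drop
in the X:autosome (X:AA) expression ratio during meiosis. Both signals are
subtle: stage-enriched samples are mixtures of neighbouring cell types, and
naive X:AA estimates are inflated by the X's deficit of lowly expressed
genes. `msciseq` provides the full analysis chain for this problem, for
anyone working with staged germline expression data (Drosophila or
otherwise), together with a ground-truth simulator to calibrate every step.

## What it computes

- **Stage contrasts** — per-gene negative binomial Wald tests of meiosis vs
  mitosis (and post-meiosis vs meiosis). Counts are normalized with
  median-of-ratios size factors, per-gene dispersions come from a
  method-of-moments fit of Var = μ + αμ², and each gene is fit with the GLM
  log μ = log s + β₀ + β₁·1(meiosis), testing β₁ = 0 with the observed
  Fisher information. Benjamini–Hochberg adjustment gives q-values and
  down/up/unchanged classes.
- **Chromosomal enrichment** — proportions of down/up genes per chromosome
  class (X, neo-X, autosomes, dot), with all annotated genes of the biotype
  as denominators, tested against autosomes by Yates-corrected chi-square:
  χ² = Σ (|O−E| − ½)² / E on the 2×2 class-by-regulated table.
- **X:AA ratios** — the matched-fraction ("filter-by-fraction") estimator:
  at each TPM threshold t ∈ {0, 2, 10}, take the smallest fraction of genes
  above t among X, (neo-X,) autosomes; extract that top-expressed fraction
  from every class; report median(top X) / median(top autosomes). A plain
  thresholded median ratio ("by expression") is computed alongside, and
  per-replicate ratios are compared across stages by Wilcoxon rank-sum.
- **Gene-age dynamics** — mean log₂ expression ± SEM trajectories by gene
  age (branch 0 = old, branches 1–6 = new) × chromosome class, with
  rank-sum contrasts (new-X vs old-X per stage, new-X vs new-autosome per
  stage, old-X mitosis vs meiosis).
- **Profiles & QC** — k-means clustering of Z-scored stage profiles
  (k = 12 by default), log₂ Pearson sample correlations, sample PCA.
- **Synthetic data** — `simulate_experiment()` draws NB counts over
  3 stages × replicates with configurable MSCI effect, age-dependent stage
  programs, library-size variation and stage-mixture impurity, plus the
  analytic expectations every recovery test needs.

## Worked example

Simulate a study-shaped experiment (4,900 genes, 3 stages × 3 replicates,
half the X silenced two-fold in meiosis, 70% stage purity), then run the
MSCI analyses:

```r
library(msciseq)

cfg <- simulation_config(seed = 11)
sim <- simulate_experiment(cfg)

fit <- de_contrast(sim$dataset, "meiosis", "mitosis")
glance(fit)
#>   contrast        n_genes n_tested n_down  n_up q_threshold
#> 1 meiosis:mitosis    4900     4851     42    33        0.05

run_enrichment(tabulate_class_counts(fit, sim$annotation))
#>   chromosome_class direction n_regulated n_total proportion  chi2        p stars
#> 1 Dot              down                0      30    0        0    1   e+ 0 ""
#> 2 X                down               22     750    0.0293  41.4  1.26e-10 "***"
#> 3 Dot              up                  0      30    0        0    1   e+ 0 ""
#> 4 X                up                  2     750    0.00267  1.58 2.09e- 1 ""
```

Although per-gene power is modest with three replicates and diluted fold
changes (the silenced genes' effective meiotic fold change is −0.5 log₂
after stage mixing), the X accumulates 2.9% down-regulated genes against
~0% on the autosomes — a highly significant excess (χ² = 41.4,
p = 1.3e-10), while upregulated genes show no X excess. The same dataset's
matched-fraction X:AA ratios dip specifically in meiosis:

```r
xaa <- xaa_stage_table(sim$dataset, sim$annotation, methods = "by_fraction")
dplyr::filter(xaa, replicate == "pooled", threshold == 2)
#>   stage        threshold f_used ratio
#> 1 mitosis              2  0.985 0.936
#> 2 meiosis              2  0.984 0.780
#> 3 post_meiosis         2  0.988 0.900
```

`stage_trajectories()` / `compare_age_location_groups()` add the age view,
`kmeans_profiles()` the expression-profile clusters, and
`run_full_pipeline(cfg, "out/")` writes every table plus a checksummed
manifest and a JSON report (`report.json` carries an `msci_flagged` verdict).
`plot_enrichment()`, `plot_xaa()`, `plot_trajectories()` and `autoplot()`
methods give the standard figures.

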