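# poolDEG

Candidate-gene discovery from pooled extreme-phenotype transcriptomics.

`poolDEG` is an R package for the bulked-segregant style of expression
analysis used to find genes behind quantitative traits in species
without reference genomes: seedlings from a segregating cross are pooled
at the two extremes of a trait (e.g. internode length or trunk diameter
in olive), the pools and reference varieties are hybridized to an
expression microarray, and genes whose expression tracks the phenotype
contrast — and stays concordant with the reference variety showing the
desired phenotype — become candidates. It is aimed at researchers
running (or re-analysing) such pooled designs who want the selection
rules, validation statistics and calibration checks as tested,
reusable code.

## The statistics at its core

* **Joint DEG rule.** Gene `g` is differentially expressed between
  groups A and B iff a two-tailed equal-variance Student t-test gives
  `p < α` (default 0.05; on log2 replicate values by default) **and**
  the fold change `x̄/ȳ` of linear group means is strictly outside
  `[1/θ, θ]` (default θ = 2). No gene-level FDR by default (optional
  BH switch).
* **Three-way concordance filter.** A candidate for a trait must be a
  DEG in the opposite-phenotype contrast (e.g. SILe vs LILe) and *not*
  significantly different (`p ≥ α`) between the reference variety and
  the like-phenotype group (e.g. Chiquitita vs SILe). Direction is the
  sign of the primary log2 fold change.
* **Set validation.** (i) Kruskal–Wallis test of per-gene, per-group
  mean log2 expression across all 9 sample groups, calibrated against
  random same-size gene sets; (ii) Poisson overlap significance for two
  candidate sets: `λ = nA·nB/N`, exact upper tail `P(X ≥ k)`, with an
  exact hypergeometric reference model alongside.
* **GO enrichment.** Per-term 2×2 two-tailed Fisher's exact test
  (point-probability rule) against the array background,
  Benjamini–Hochberg FDR, optional true-path propagation.
* **qPCR concordance.** ΔCt relative expression
  `2^-(Ct_target − Ct_actin)`, Pearson correlation of qPCR vs array
  log2 ratios against the analytic critical value
  `t/√(t² + df)` (0.708 at n = 12, α = 0.005, single-tail), and one-way
  ANOVA + 95% LSD letter grouping for per-seedling comparisons.
* **Synthetic data with planted truth.** A generator reproducing the
  9-group × 3-replicate design (log-normal baselines, Gaussian log2
  replicate noise, trait effects shared between reference variety and
  like-phenotype pool) so recovery, calibration and determinism are all
  testable.

## Worked example

```r
library(poolDEG)

cfg    <- pipeline_config(out_dir = "demo_run", seed = 42L,
                          n_genes = 5000L, n_random = 200L)
bundle <- simulate_bundle(cfg)                     # expression + truth + Ct
res    <- run_pipeline(bundle$matrix, config = cfg,
                       truth = bundle$truth, ct_table = bundle$ct)

res$venn$sizes
#> internode_length   trunk_diameter     growth_habit
#>               49               46               48
res$venn$union_size
#> [1] 143
res$recovery[c("trait", "n_selected", "recovered", "recall", "precision")]
#>              trait n_selected recovered recall precision
#> 1 internode_length         49        49   0.98         1
#> 2   trunk_diameter         46        46   0.92         1
#> 3     growth_habit         48        48   0.96         1
res$qpcr$concordance[c("r", "r_critical", "significant")]
#> $r
#> [1] 0.9934943
#> $r_critical
#> [1] 0.7078876
#> $significant
#> [1] TRUE
```

Each trait plants 50 concordant genes at |log2 effect| 1.5; the
three-way selection recovers 92–98% of them with no false positives
here (the structural ceiling is 1 − α ≈ 95% on average, because the
concordance filter falsely rejects an α fraction of true candidates —
see the vignette). All reports (contrast tables, candidate TSV, Venn
counts, overlap and Kruskal–Wallis validation JSON, qPCR concordance,
recovery metrics, run manifest) are written under `cfg$out_dir`, and a
rerun with the same seed is byte-identical.

The published 27-seedling phenotype table ships with the package:

```r
ph <- load_phenotypes(system.file("extdata", "seedling_phenotypes.tsv",
                                  package = "poolDEG"))
mean_internode_length(as.numeric(ph[1, paste0("branch", 1:5, "_mm")]),
                      rounded = TRUE)
#> [1] 2.7
```

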