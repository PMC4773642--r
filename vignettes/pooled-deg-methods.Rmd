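---
title: "Pooled extreme-phenotype candidate-gene discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled extreme-phenotype candidate-gene discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolDEG)
```

# The analysis problem

Olive is a tree crop whose traditional varieties have canopies poorly
suited to high-density orchards. Plant-architecture traits — internode
length, trunk diameter, overall growth habit — are heritable but hard to
map in a long-lived, largely unsequenced species. A pragmatic
transcriptomic shortcut is a bulked-segregant style design: from a
segregating progeny, seedlings at the two extremes of a quantitative
trait are pooled, RNA from each pool is hybridized to an expression
microarray, and genes whose expression tracks the phenotype contrast
become candidates.

`poolDEG` implements that full analysis as a reusable, tested pipeline:
extreme-phenotype pool construction from seedling measurements, per-gene
differential-expression calling under a joint fold-change / *t*-test
rule, a three-way concordance filter against a reference variety,
Venn/union assembly of candidate sets, two resampling-style validation
statistics, a generic GO-term enrichment engine, and qPCR concordance
checks — together with a synthetic-data generator with planted truth so
every stage can be exercised and calibrated without the original
hybridization data.

The default study design is nine sample groups with three biological
replicates each: four varieties (Chiquitita — the compact, weeping
reference phenotype — Picual, Arbequina, Arbosana) and five seedling
pools (SILe/LILe: short/long internode length; SmaD/LarD: small/large
trunk diameter; ChiCa: Chiquitita-like canopy). The array universe at
full scale is 37449 unigenes.

# Phenotyping and pool construction

Each seedling contributes a trunk diameter (mm, at 1 m height) and five
branch-level mean internode lengths (mm); the seedling-level internode
trait is the arithmetic mean of the five branch values
(`mean_internode_length()`). Display rounding is half-up to two
decimals, matching how such phenotype tables are printed; full precision
propagates internally. The package ships the 27-seedling measurement
table of the source study (`inst/extdata/seedling_phenotypes.tsv`);
recomputing the derived trait column reproduces every printed value at
two decimals.

`select_extreme_pools()` takes the `k` lowest and `k` highest seedlings
by a chosen trait. Ties are broken by input row order, which makes
selection deterministic; the published design used pools of 4–6
seedlings (SILe 6, LILe 5, SmaD 6, LarD 5, ChiCa 5). Canopy-shape
(ChiCa) membership is a visual classification and therefore an input
label, never computed.

# The DEG model

For groups $A$ and $B$ with replicate intensities on a linear scale, a
gene is called differentially expressed iff both:

* two-tailed equal-variance Student *t*-test, $p < \alpha$ (default
  $\alpha = 0.05$, $df = n_A + n_B - 2$), and
* fold change $\bar x/\bar y$ of the *linear* group means strictly
  outside $[1/\theta, \theta]$ (default $\theta = 2$; "more than"
  two-fold, so a ratio of exactly 2 does not qualify).

No gene-level multiple-testing correction is applied by default — the
raw per-gene $\alpha$ is the fidelity-preserving choice for this
design, with FDR control belonging to the enrichment stage. An optional
Benjamini–Hochberg switch (`bh = TRUE`) is provided for stricter use.

The scale of the *t*-test is configurable (`test_scale`): the default is
log2-transformed replicate values (the standard variance-stabilizing
choice for intensities), with `"linear"` available because the original
description states the fold change as a ratio of means but not the test
scale. Neither is asserted to be the historical computation.

Degenerate genes (zero pooled variance) get $p = 1$ when group means are
equal and $p = 0$ with a warning when they differ, so constant fixtures
have defined behavior.

## The three-way concordance filter

Each trait is analysed as a contrast triple: a **primary** contrast
between opposite-phenotype groups (SILe vs LILe; SmaD vs LarD;
Chiquitita vs Arbosana) and a **concordance** contrast between the
reference variety and the like-phenotype group (Chiquitita vs SILe;
Chiquitita vs SmaD; Chiquitita vs ChiCa). A candidate gene must be a DEG
in the primary contrast *and* not significantly different in the
concordance contrast. "Not significantly different" is read purely as
$p \ge \alpha$, ignoring fold change — the filter is phrased as a
significance condition, and that reading keeps it one-parameter.

An important structural consequence, verified by the test suite: because
the concordance contrast is an *exact* null for a truly concordant gene,
its p-value is Uniform(0,1) at any noise level, and the filter falsely
discards an $\alpha$ fraction of true candidates no matter how good the
data. The recovery ceiling of the three-way rule is therefore
$1-\alpha \approx 95\%$, not 100% — the noise-free limit recovers every
planted gene at the primary stage but still loses $\sim$5% to the
concordance test.

Candidate sets from the three traits are assembled by exact
inclusion–exclusion (`venn_summary()`); with the published set sizes
(23, 299, 1957) and overlaps (4 between internode and habit, 23 between
diameter and habit, none elsewhere) the union is exactly 2252 genes.

# Validation statistics

## Random-set Kruskal–Wallis null

`kw_set_validation()` asks whether a candidate set's expression varies
across the nine sample groups more than a random same-size gene set
would. The observation unit is the per-gene, per-group mean of log2
expression over replicates, with the nine groups as the Kruskal–Wallis
factor; random sets are drawn uniformly without replacement from the
full gene universe under a seeded generator (default 1000 draws). The
phrase "median expression values across all samples" admits several
readings; this one makes genes the observations and reproduces the
qualitative published contrast (trait sets significant, random sets
not).

Two calibration facts matter. First, with per-gene baselines spread
realistically (log2 sd 2), the pooled-rank test is *conservative* for
small sets: gene-to-gene baseline variation dominates the ranks, and
a 60-gene set with a 1-log2-unit group shift is not significant — which
mirrors the original study's own finding that its smallest (23-gene)
set failed this validation while the 299- and 1957-gene sets passed.
The signal test in this package therefore uses a 299-gene set. Second,
the "random sets behave like the null at rate $\alpha$" property only
holds when all observations are exchangeable; the calibration test
uses a flat-baseline simulation for exactly that reason.

## Overlap significance

The overlap $k$ of two candidate sets of sizes $n_A, n_B$ in a universe
of $N$ genes is modelled as Poisson with rate $\lambda = n_A n_B / N$
(the expected overlap under independent uniform draws);
`poisson_overlap_p()` reports the exact upper tail $P(X \ge k)$ by
direct series summation (no normal approximation, no
one-minus-lower-tail cancellation). `hypergeometric_overlap_p()` is the
exact reference model for a random subset against a fixed subset; the
two agree within a few percent whenever $n_A, n_B \ll N$.

With the published sizes (23 and 1957, $N = 37449$, $k = 4$) this
Poisson model gives $\lambda = 1.202$ and $P = 0.034$, and the
diameter–habit pair (299, 1957, $k = 23$) gives $P = 0.047$; the
originally printed values (0.0078 and 0.029) are not reproducible from
this construction, whose universe and tail convention were never
specified. Notably, the *hypergeometric* tail for the internode–habit
pair is 0.0297 — numerically matching one of the printed values —
suggesting the original computation may have used a different model or
ordering. The package reports its own clearly defined statistics rather
than guessing; reproducing the printed overlap p-values is explicitly
not a goal.

# GO enrichment engine

`enrich()` is a generic over/under-representation engine: for every
term annotated in the background, a 2×2 table (candidate genes
with/without the term versus remaining background genes with/without
it), a two-tailed Fisher's exact test, and Benjamini–Hochberg adjustment
over all tested terms with a default significance filter of
$q < 0.05$. The two-sided p-value uses the point-probability rule — sum
the hypergeometric probabilities of all tables with the observed margins
whose point probability does not exceed the observed one, compared with
a $10^{-7}$ relative tolerance — which is the dominant convention. The
background defaults to whatever universe the caller supplies (all genes
on the array, or all annotated genes); only directly assigned terms are
tested unless an ontology edge list (child, parent) is supplied, in
which case true-path propagation to ancestors is applied first. Because
the original annotation provenance and propagation settings are
unknown, enrichment of the real candidate lists is not a validation
surface; the engine is validated against exhaustive enumeration and
FDR-calibration simulations instead.

# qPCR concordance

Relative expression uses the ΔCt method,
$2^{-(\bar{Ct}_{target}-\bar{Ct}_{reference})}$ against constitutive
actin, with amplification efficiency assumed exactly 2 per cycle.
Technical triplicates are averaged at the Ct level; biological
replicates are summarized as the mean of log2 relative expression,
preserving the geometric structure of ratios (the aggregation order is
not stated in the source method, so this is a package choice).

Method concordance is the Pearson correlation of paired log2 ratios
(qPCR vs microarray) compared with the analytic critical value
$r_{crit} = t_{\alpha,df}/\sqrt{t^2_{\alpha,df}+df}$, $df = n-2$. The
single-tail convention is the default because it reproduces the
published critical value 0.708 at $n = 12$, $\alpha = 0.005$; two-tail
is available.

Per-seedling expression comparisons use one-way ANOVA followed, when
significant, by pairwise Fisher LSD at 95% with letter-group summaries.
Letters are assigned by maximal cliques of the "not significantly
different" graph rather than by intervals along the mean ordering:
with unequal group sizes the per-pair LSD varies, the relation need not
be interval-like, and the clique cover is the assignment that is exactly
consistent with every pairwise decision (the suite checks it against
the full pairwise matrix). The ANOVA unit is the biological replicate;
pooling technical replicates into the error term is deliberately
avoided.

# The synthetic-data generator

`simulate_expression()` draws linear-scale intensities
$2^{(b_g + e_{gs} + \varepsilon)}$: a per-gene baseline
$b_g \sim N(8, 2^2)$ shared across groups (preserving gene-wise pairing),
additive group effects $e_{gs}$ for planted genes, and i.i.d. Gaussian
replicate noise on the log2 scale (default sd 0.2, consistent with the
high replicate correlations the design requires). Planted sets are
disjoint across traits, with alternating effect signs (default 50
concordant genes per trait at $|\log_2| = 1.5$). The concordance rule is
built in: a concordant gene carries the identical effect in the
reference variety and the like-phenotype pool, leaving the opposite pool
at baseline; a discordant gene carries the effect in the like-pool but
the opposite effect in the reference, so the three-way filter should
reject it. Pools are simulated as single averaged RNA samples per
replicate, as they were hybridized.

What the generator does *not* model: probe-level effects, dye bias,
normalization artifacts, correlated noise between replicates, and the
physical RNA mixing of pool members (a pool is just a group). Passing
tests therefore demonstrate the correctness and calibration of the
*statistics* under the stated noise model, not robustness to real
microarray artifacts.

Phenotype simulation draws trunk diameter ($N(75, 20^2)$ mm) and branch
internode means ($N(1.8, 0.5^2)$ mm) per seedling — values matching the
range of the published 27-seedling table — for a default progeny of 120
seedlings, the size of the source cross. Ct simulation writes
$Ct_{target} = Ct_{ref} - \log_2(\text{ratio}) + \varepsilon$ with
technical-by-biological replicate structure, so the noiseless table
inverts the ΔCt transform exactly.

# Numerical and design choices

* **Strict inequalities** throughout the DEG rule: $p < \alpha$ and fold
  change strictly outside $[1/\theta,\theta]$.
* **Poisson tail**: upward series summation with a multiplicative term
  recurrence, accurate at extreme tails where $1-\mathrm{CDF}$ cancels;
  matches an independent CDF evaluation to $10^{-12}$ for
  $\lambda \le 50$, $k \le 100$.
* **Rounding** of displayed phenotype means: half-up at 2 decimals,
  display-only.
* **Tie-breaks** in pool selection: stable input row order.
* **Seeding**: one top-level seed; stages derive sub-seeds by fixed
  documented offsets, so end-to-end runs are byte-identical under a
  fixed seed (the suite checks file-level identity).
* **Problem sizes** in tests and the acceptance script: 2000–5000
  simulated genes, 10–20 seed replicates for calibration sweeps, 1000
  random sets for the Kruskal–Wallis null — sizes chosen so the whole
  suite runs in well under a minute on a laptop core while keeping
  Monte-Carlo error around a percent on the rates being asserted.
* **Command-line surface**: the package is an analysis library; the
  exported functions `simulate_bundle()` / `run_pipeline()` and the
  repository script `scripts/acceptance.R` are the intended entry
  points, rather than a shell subcommand wrapper.

# Known limitations

The genome-scale candidate counts of the source study (201 and 896
primary DEGs; 23, 299, 1957 three-way candidates) depend on the original
hybridization data (GEO accession GSE60284) and are deliberately not
reproduction targets. The Kruskal–Wallis reading of "median expression
values" is one of several defensible interpretations; the printed
overlap p-values come from an underspecified model and are reported
under this package's own definitions instead. GO enrichment on real
annotations depends on propagation and background choices the package
exposes but cannot recover from the original suite.
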