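---
title: "Statistical methods behind the triomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the triomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

# Overview

`triomics` integrates matched transcriptomic, proteomic and metabolomic
measurements of a two-group contrast (e.g. a toxic-insult versus control
nerve-cell experiment) through five analytic stages: per-omic moderated-t
differential expression, preranked gene-set enrichment with a cross-omics
direction consensus, a resampling test for subcellular-compartment
association, deterministic painting of a metabolic reaction graph, and PCA
with group confidence ellipses. Because real multi-omics studies rarely
come with ground truth, the package ships a synthetic tri-omics generator
with planted effects so that every stage can be calibrated and its
recovery quantified.

# Per-omic preprocessing

Each omic gets the preparation its measurement process requires:

* **Transcriptome** — raw counts are divided by *median-of-ratios size
  factors* (for each sample, the median over features of the count divided
  by the feature's geometric mean across samples, restricted to features
  expressed in every sample), then transformed as `log2(x + 1)`.
* **Proteome** — normalized spectrum intensities are transformed as
  `log2(x + 5)`. The pseudo-count of 5 damps the relative noise of
  low-spectral-count proteins, which is much larger than for counts of
  reads; 1 suffices for the deeply sampled transcriptome.
* **Metabolome** — missing values are treated as below the detection
  limit and imputed with the *compound minimum* (the smallest observed
  value of that compound), then `log2(x + 1)` transformed. Minimum
  imputation is the standard left-censoring treatment for targeted
  metabolomics panels; it is idempotent and order-independent.

All logarithms in the package are base 2, so a `logFC` threshold of 0.5
reads as a fold change of about 1.41.

Batch structure in the proteome (a consequence of multiplexed isobaric
labeling) is handled in two ways. For hypothesis testing, batch enters the
per-feature linear model as a covariate. For PCA, the log matrix is
*batch mean-centered*: per feature, each batch's mean is subtracted and
the grand mean re-added. With a group-balanced batch layout this removes
additive batch location effects — the only component the downstream
projection and consensus logic depend on — while deliberately not
attempting empirical-Bayes scale adjustment of batch variances; the
centering is an exact projection (applying it twice changes nothing),
which keeps the pipeline's determinism contract easy to state and verify.

# Differential expression

For every feature the package fits ordinary least squares of the log2
value on an intercept, a treated-group indicator and optional batch
indicators. The group coefficient is the log2 fold change (treated minus
control). Residual variances are then shrunk by an empirical-Bayes step:
assuming `s2 ~ s0^2 * F(d, d0)` across features, the prior degrees of
freedom `d0` and prior variance `s0^2` are estimated by moment-matching
the mean and variance of `log(s2)` through digamma/trigamma inversion,
and each feature receives the posterior

```
s2_post = (d0 * s0^2 + d * s2) / (d0 + d)
```

The moderated t statistic `effect / (sqrt(s2_post) * leverage)` is
referred to a Student-t distribution with `d0 + d` degrees of freedom.
The test suite verifies that the hyperparameter recovery is accurate on
scaled-F draws (within 20% for `d0`, 10% for `s0^2` at 5000 features),
that the engine agrees with an independent empirical-Bayes implementation,
and that it collapses to the ordinary two-sample t-test when moderation is
switched off. One engine serves all three omics; this is a deliberate
simplification relative to count-specific negative-binomial Wald tests,
trading a little transcriptome power for a single well-specified,
self-contained procedure whose null calibration is demonstrated directly
(raw p-values are uniform within KS distance 0.05 on 2000-feature null
simulations).

A feature is called differentially expressed iff `FDR < 0.05` **and**
`|logFC| > 0.5`, both inequalities strict. FDR is Benjamini–Hochberg.
Features with zero residual variance even after moderation ("exact fits",
possible when minimum imputation makes a row nearly constant) are flagged
and excluded from ranking rather than given p = 0.

# Preranked enrichment and the cross-omics consensus

Features are ranked by `sign(logFC) * (-log10 p)`, descending, with ties
broken by `|logFC|` and then feature id so the list is deterministic. For
a gene set, the enrichment score (ES) is the signed maximum deviation of
the weighted running sum: set members increment by
`|score|^w / sum(|score in set|^w)` (default weight `w = 1`), non-members
decrement by `1/(N - n_set)`. At `w = 0` this is the classical
Kolmogorov–Smirnov statistic and the running sum terminates at zero; both
properties are asserted on random instances, and the fast
evaluated-at-hits implementation used inside permutations is checked
against an explicit element-by-element walk and against an independent
GSEA implementation.

Because only a ranked list per omic is available at this stage, the null
is built from *random feature sets of matching size* (1000 by default),
not phenotype permutation. Normalization and inference are
sign-stratified: `NES = ES / mean(|null ES| of the same sign)`, and the
permutation p-value is one-sided within the observed sign with an add-one
correction, `(1 + exceedances) / (1 + same-sign nulls)`. The
stratification is what makes the p-value approximately uniform for a
random set — a property the test suite asserts (KS distance < 0.1 over
200 random sets) — while an all-permutation denominator would bound it
near 0.5. The price is that the attainable floor is roughly
`2/n_perm` rather than `1/(n_perm + 1)`; p is never exactly 0 either way.
FDR is the usual sign-stratified ratio of null to observed NES tail
fractions, also with an add-one correction on the null tail so that
`-log10(FDR)` stays finite. Sets are filtered to an effective size
(intersection with the ranked list) between 5 and 500, a conventional
range. Metabolites are excluded from enrichment: they have no gene
equivalent, so gene-set membership is undefined for them.

The cross-omics consensus intersects the transcriptome and proteome
results: a pathway is consensus-significant iff it has `FDR < 0.1` in
*both* omics with the *same* direction; discordant directions are
excluded. Records carry the average of the two `-log10(FDR)` values and
are ranked by it; Venn-style counts of omic-exclusive and shared sets are
reported alongside.

# Compartment association

The association of a DE set with a subcellular compartment is the
*overlap ratio*: DE features annotated to the compartment divided by all
universe features annotated to it. Significance comes from a resampling
null: B = 1000 draws (by default) of `|DE|` features from the tested
universe, every compartment scored against the *same* draw matrix, and

```
p_emp = (1 + #{draws with null ratio >= observed}) / (B + 1)
```

Draws are **without replacement**: drawing a DE-sized candidate set from
the reference total describes a permutation-style null, under which the
overlap count is exactly hypergeometric. That identity gives the package
its oracle: `hypergeometric_oracle()` sums the exact tail terms, and the
acceptance suite verifies `|p_emp - p_exact|` stays within three
Monte-Carlo standard errors at B = 10000 on ≥ 99% of randomized
instances. With-replacement draws are available as an option but carry no
such guarantee. No multiple-testing correction is applied across
compartments — the per-compartment empirical p is reported raw — and
features may belong to several compartments, each tested marginally.

# Metabolic-map painting

Reaction edges carry gene/protein evidence; metabolite nodes are the
substrates and products. The painting rule uses direction only, never
magnitude: every DE evidence feature on an edge is one vote, all-up gives
red, all-down gives blue, any disagreement (including a gene and its own
protein product disagreeing) gives purple, and no DE evidence leaves the
edge unpainted. The four states are exhaustive and mutually exclusive,
which the suite asserts by enumerating every evidence configuration. DE
metabolite nodes are colored by sign with gradient intensity
`min(|logFC|, cap)/cap`; the cap (default 3, i.e. 8-fold) keeps a single
extreme metabolite from flattening the visual scale. How multiple enzymes
on one reaction line should be aggregated is genuinely open; the
all-votes rule was chosen because it is the unique symmetric rule that
reduces to the stated two-feature semantics.

# PCA and confidence ellipses

PCA is computed by SVD of the per-feature centered matrix; variance
explained is `sigma_k^2 / sum(sigma^2)`, and each component's sign is
fixed by making its largest-magnitude loading positive. The transcriptome
and proteome are projected on their top 500 most *variable* features
(the proteome after batch centering); the metabolome uses all compounds.
Variance-based selection was chosen over expression-based selection
because separation between groups is driven by dispersion, not abundance;
an expression-ranked option exists but carries no fidelity claim. Group
ellipses use the classical bivariate Student/Hotelling scaling: center at
the group mean, axes along the eigenvectors of the 2×2 sample covariance
with semi-axes `sqrt(lambda_j) * sqrt(2 * qF(0.95; 2, n-2))`. Classical
rather than robust covariance is used; with n = 4–5 per group a robust
estimate would be meaningless. Collinear scores produce a flagged
degenerate ellipse (a segment), not an error.

# The synthetic generator

`generate_universe()` builds the annotation scaffolding: gene, protein
and metabolite id universes (proteins are the products of a random gene
subset and share gene ids, so one gene-set collection serves both omics),
KEGG-like gene sets, overlapping compartments, and a reaction graph with
namespaced evidence. `plant_truth()` decides what is true:

* background DE genes, sampled with per-compartment selection weights
  (a weight of w makes members w times as likely to be picked — this is
  how compartment enrichment is planted);
* coherent pathway effects: a fraction (default 0.6) of a planted
  pathway's members receive a common-sign log2 effect;
* metabolite effects, batch offsets, and the planted effect size
  (default 2, a 4-fold change typical of a strong toxic insult).

The simulators then realize that truth: negative-binomial counts with
fixed dispersion 0.1 (the simplest over-dispersed RNA-seq model;
per-sample library factors in 0.7–1.3 exercise the normalization),
log2-normal spectrum intensities with additive batch offsets (residual SD
0.5), and log2-normal metabolite abundances (SD 0.5, a Metabolon-like
replicate spread) with *left-censored* missingness: each compound's
detection limit sits at the target quantile of its baseline distribution,
so overall missingness matches the target while planted down-effects push
extra treated-group values below the limit — the missing-not-at-random
mechanism minimum imputation is designed for. The missingness rate has no
claimed real-data fidelity and is exposed as a parameter (default 0.15).
Each omic consumes its own RNG stream derived from the master seed, so
omics can be regenerated independently and the whole pipeline is
byte-reproducible given a seed.

What the generator does **not** emulate: read- or spectrum-level physics,
correlated feature blocks beyond pathways, signal-dependent
mean–variance trends, or real KEGG/atlas content. Passing tests therefore
demonstrate calibration and recovery under a clean, known model — not
performance on any particular real dataset.

# Default constants and problem sizes

| Constant | Default | Where |
|---|---|---|
| DE thresholds | FDR < 0.05, &#124;logFC&#124; > 0.5 (strict) | `call_de()` |
| Enrichment significance | FDR < 0.1 | `preranked_gsea()` |
| GSEA permutations | 1000 | `preranked_gsea()` |
| Resampling draws | B = 1000 | `bootstrap_compartment_test()` |
| Set-size filter | [5, 500] | `preranked_gsea()` |
| PCA feature selection | top 500 by variance | `top_variable_features()` |
| Gradient cap | &#124;logFC&#124; = 3 | `paint_nodes()` |
| NB dispersion | 0.1 | `simulate_transcriptome()` |
| Planted effect size | 2 (log2) | `plant_truth()` |

The test and acceptance suites run at deliberately compact sizes chosen
to keep every check sharp but fast: null calibration on 2000-feature
universes over 20 seeds; hyperparameter recovery at 5000 features;
oracle-vs-bootstrap comparison at B = 10000 over 100 randomized
instances; pathway recovery on 400-gene/200-protein universes with
pathways of 20–60 members (the typical size of a curated pathway; a
pathway leaving fewer than 5 measured proteins after intersection is
below any sensible set-size filter) over 20 seeds; and the end-to-end
default configuration at 1000 genes / 400 proteins / 200 metabolites.

At the study's group sizes (n = 5/group) and dispersion, a solitary log2
effect of exactly 1 has only ~65% post-BH power, so single-feature
sensitivity above 0.8 is a property of effects at the planted default
magnitude of 2, not of the 1.0 boundary; this is a power fact about the
design, documented here rather than hidden behind a looser test.

# Known limitations

* Minimum imputation attenuates strong down-effects: when a planted
  decrease pushes essentially every treated value below the detection
  limit, the imputed treated values equal the compound's observed minimum
  (typically a low control value), capping the observable log2 fold
  change near the control minimum minus the control mean (about −0.5 at
  the default noise level). Large planted decreases can therefore fall
  under the |logFC| > 0.5 cut — a real and well-known property of
  left-censoring plus minimum imputation, visible in the synthetic runs
  as up-biased metabolome DE calls.
* The moderated-t engine applied to log-normalized counts diverges from
  negative-binomial Wald testing at very low counts; the package does not
  implement dispersion shrinkage, independent filtering or logFC
  shrinkage.
* The random-set GSEA null is less conservative than phenotype
  permutation when features are strongly correlated within sets.
* Batch mean-centering ignores multiplicative batch effects.
* The metabolome test is the same moderated-t as the other omics; no
  claim is made that it matches any proprietary platform's statistics.
* Published compartment analyses of this kind quote specific random seeds
  (e.g. 10 for gene data, 100 for protein data); such seeds are recorded
  as configuration metadata, but bit-level reproduction across RNG
  implementations is not claimed — only distributional equivalence, which
  the hypergeometric oracle verifies.
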