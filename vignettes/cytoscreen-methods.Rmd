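---
title: "Methods: survival screening of expression biomarkers with cytoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival screening of expression biomarkers with cytoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The problem

In aggressive tumors such as glioblastoma, chronically elevated cytokine
signaling shapes the tumor microenvironment, and which cytokine/receptor
axes matter clinically can be asked directly of cohort data: for each
candidate gene, do patients expressing it highly die (or progress) sooner?
cytoscreen implements that question as a reproducible screening pipeline
over a genes-by-patients expression matrix and a clinical table of
right-censored endpoints — overall survival (OS) and, when available,
disease-free survival (DFS), both in months.

Because a cytokine only signals through its receptor, the screen does not
stop at single genes: each ligand's evidence is combined with its
receptor's into one score per signaling axis, so an axis whose two ends
are independently prognostic rises above genes that are strong alone but
have no partner support.

## The screening model

### Dichotomization

For each gene the cohort is split at the *mean* of its (Z-scored)
expression: `high` if the value strictly exceeds the mean, `low`
otherwise. A value exactly at the mean goes to `low`; this tie rule is
measure-zero on real data but makes fixtures deterministic. A second,
band-based stratifier is available for single-gene analyses: patients with
Z-score above 0.25 are `high`, below −0.25 `low`, and the band in between
is excluded. The two thresholds must differ strictly so the excluded band
is well defined; for an empty band, the mean split is the right tool.

### Survival comparison

The high/low comparison is made twice for every gene:

* **Cox proportional hazards** for the binary group indicator \(x\):
  hazard \(\lambda(t \mid x) = \lambda_0(t)\, e^{\beta x}\). The partial
  likelihood is maximized by Newton–Raphson on the scalar \(\beta\);
  the reported p-value is the two-sided Wald test
  \(z = \hat\beta / \widehat{\mathrm{se}}(\hat\beta)\) with the standard
  error from the observed information. The hazard ratio
  \(e^{\hat\beta}\) reads as the relative event rate of high vs low
  expressors.
* **Logrank test**: at each distinct event time the expected number of
  events per group is the hypergeometric mean \(d\,n_g/n\) and the
  variance the hypergeometric variance
  \(d (n-d) n_1 n_0 / (n^2 (n-1))\); the statistic
  \((O - E)^2 / V\) is referred to \(\chi^2_1\).

Both p-values appear in every screen table; a configuration switch
(`test = "cox"` default, or `"logrank"`) selects which one ranks genes.
The two usually agree closely — the logrank test is the Cox score test —
but they are not identical, and both views of the evidence are kept.

Ties in month-resolution survival data are frequent, so the Cox fit uses
the **Efron** correction by default; **Breslow** is available because it
is the natural partner for brute-force oracle checks (and exactly equals
Efron on tie-free data, which the tests assert to 1e-9). Convergence is
declared when the absolute score falls below 1e-9 (at most 50
iterations). A monotone likelihood — all events stacked in one group's
favor — has no finite maximizer; \(\hat\beta\) is then capped at ±20 and
flagged `converged = FALSE`, and screening code treats the gene's
direction call as undefined rather than reporting a fake hazard ratio.

P-values are two-sided and reported raw; the α = 0.05 significance flag
is a downstream filter, not baked into the statistics. Because raw
per-gene p-values invite multiplicity abuse, Benjamini–Hochberg q-values
are additionally attached to every screen, clearly separated in their own
column.

### Combined ligand–receptor rank

Genes are ranked by ascending ranking p-value (average ranks on ties).
For each ligand with mapped receptor(s), the receptor ranks are first
aggregated, then combined with the ligand's rank, both with the same
rule. The default rule is the **mean** of the two ranks — it preserves
scale across panels of different size — with `sum` and `best` (minimum)
exposed as alternatives since a rank "combination" admits all three
readings. Final ordering is ascending by combined score with a
deterministic tie-break on ligand id. Ligands whose receptors were all
unscreened are excluded and reported, never silently dropped.

### Iterative Kaplan–Meier filtering

`iterative_km()` applies the same per-gene machinery to an arbitrary gene
list (e.g. the targets of a transcription factor) and keeps the genes
with p below α, each labeled `poor` (hazard ratio of high expressors
above 1) or `good`. The poor/good proportion among survivors is reported,
which is the quantitative form of statements like "most prognostic genes
in this program mark poor outcome".

### Zygosity and joint stratification

GISTIC-style integer copy-number calls map to zygosity labels (−2 deep
deletion, −1 heterozygous loss, 0 diploid, +1 gain, +2 amplification),
with group frequencies reported — e.g. the fraction of tumors that lost
one allele of a deacetylase gene. Joint two-gene stratification crosses
the band-based calls of two genes into four cells; which cells form the
two comparison groups is an explicit configuration choice
(`compare = list(group1 = ..., group2 = ...)`, with `"rest"` as a
shorthand), because a 2×2 cross admits several defensible contrasts and
the package does not privilege one silently.

## The synthetic cohort generator

Real tumor-cohort data cannot ship with a package, so every procedure is
exercised against a generator whose ground truth is known exactly:

* **Expression**: independent standard-normal genes; each planted
  ligand–receptor pair is drawn bivariate normal with correlation ρ.
  The default emulation target for a strongly co-expressed cytokine pair
  is ρ = 0.77, the kind of correlation seen between co-regulated
  inflammatory cytokines in glioma cohorts.
* **Survival**: exponential baseline with hazard λ·exp(Σ effects), where
  each planted gene contributes β·1[expression above the cohort mean] and
  each configured copy-number state its own log-hazard term. The hazard
  acts on the *dichotomized* indicator, not the continuous Z-score, so
  exp(β) is exactly the estimand of the screen's Cox fit — parameter
  recovery is then a sharp test, not an approximation. A Weibull shape
  parameter is exposed (default 1 = exponential, keeping closed-form
  medians for oracle checks).
* **Censoring**: the minimum of an administrative horizon and an
  independent exponential dropout time; the censoring fraction is
  monotone in the dropout rate by construction.
* **Defaults**: 208 patients (a typical glioblastoma cohort size);
  baseline hazard 0.05/month, i.e. a ~14-month baseline median survival,
  matching glioblastoma OS; horizon 60 months; dropout 0.01/month; DFS
  hazard multiplier 1.5 (progression precedes death). These defaults are
  the study conditions of the test suite and are not tuned per test.
* **Determinism**: all sampling flows from the single config seed;
  identical config + seed reproduces the cohort byte-for-byte through the
  writers.

What the generator does **not** emulate: expression subtype structure,
batch effects, realistic genome-wide correlation beyond the planted
blocks, or informative censoring. Passing tests therefore demonstrate
statistical correctness and calibration of the machinery, not that any
particular real-cohort finding is reproduced.

## Numerical and design choices

* Z-scoring uses the sample standard deviation (n − 1); constant genes
  are set wholly missing and reported rather than producing infinities.
  The package normalizes within-cohort; public portals sometimes Z-score
  tumors against a reference population instead, so imported Z-scores and
  recomputed ones can differ systematically. Reading pre-normalized data
  is supported via the `normalized` flag.
* Missing expression values are excluded pairwise per computation, never
  imputed; every operation reports the effective n it used. Sample-id
  intersection across tables is taken automatically but logged with
  counts, since real cohort exports rarely agree exactly on patient sets.
* The enrichment test is the exact one-sided hypergeometric tail over a
  gene-set library, with the universe defined as the genes present in the
  expression matrix after QC (standard enrichment hygiene). Composite
  enrichment scores that depend on a tool's internal background ensembles
  are deliberately not reproduced; ranking is by p, then q.
* Differential expression between stratified groups is a plain Welch
  two-sample test with BH correction — an intentionally unmoderated
  choice: with ~100 patients per group the per-gene variance is well
  estimated and the result does not depend on an empirical-Bayes prior.
  The "upregulated in high" call uses q < 0.05 and positive mean
  difference by default; both knobs are explicit configuration.
* OS is the default endpoint everywhere; DFS is used where the question
  is time to progression (e.g. zygosity comparisons), and every screen
  accepts either.

## Problem sizes in the test suite

The suite validates the estimators against independent brute-force
oracles (explicit risk-set loops, naive partial-likelihood maximization
by golden-section search, exact hypergeometric tail enumeration) on
1,000+ random instances; calibrates the logrank test's type-I error on
2,000 null replicates of n = 100 and the screen's p-value uniformity on a
2,000-gene null cohort; and checks parameter recovery at n = 5,000 (Cox
hazard ratio within 10%) and the planted-pair combined-rank top-1
property over 100 seeded replicates of the 51-pair, n = 208 design. These
sizes were chosen to make sampling error small relative to each property
being asserted while keeping the default test run fast.

## Known limitations

Single binary covariate only — no multivariate or stratified Cox, no
time-varying covariates, no proportional-hazards diagnostics; the screen
inherits the usual caveats of mean-dichotomization (information loss,
cutpoint sensitivity); no multiple-testing correction is applied to the
*ranking* itself (faithful to common practice in signature screens), only
reported alongside; and the synthetic cohorts are deliberately simpler
than real tumor data, as described above.
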