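# cytoscreen

Prognostic survival screening of cytokine and receptor expression in
tumor cohorts.

## What it is for

In tumors with chronic inflammation — glioblastoma being the archetype —
a practical clinical question can be asked directly of cohort data: for
which cytokine/receptor signaling axes do highly-expressing patients die
or progress sooner? `cytoscreen` answers it with a reproducible pipeline
for biostatisticians and computational biologists working with
cBioPortal-style exports: a genes × patients expression matrix, a
clinical table of right-censored overall survival (OS) and disease-free
survival (DFS) in months, and optionally a GISTIC-style copy-number call
table.

The survival machinery is implemented from first principles so every
screening p-value is auditable:

* **Kaplan–Meier** product-limit estimate
  S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i), with median survival as the smallest
  event time where S ≤ 0.5;
* **logrank test** from the hypergeometric moments at each event time,
  χ² = (O − E)²/V on 1 df;
* **Cox proportional hazards** for a binary covariate,
  λ(t|x) = λ₀(t)·e^{βx}, maximized by Newton–Raphson with Efron
  (default) or Breslow tie handling; hazard ratio e^β, Wald p.

On top of it sit the screening procedures: per-gene mean-dichotomized
survival screens with Benjamini–Hochberg q-values; the **combined
ligand–receptor rank score** (each ligand's p-value rank merged with its
receptor's, mean/sum/best aggregation); **iterative Kaplan–Meier**
filtering of gene lists with poor/good direction calls; dual-marker
(concordant both-high vs both-low) comparison; Z-score band and
copy-number **zygosity stratification**; genome-wide index-gene Pearson
correlation ranking; and exact hypergeometric gene-set enrichment over
GMT libraries. A seeded synthetic-cohort generator with planted
proportional-hazards effects makes every stage testable against known
ground truth.

## Worked example

Generate the standard synthetic fixtures (a cohort of 208 patients with
one planted prognostic ligand–receptor pair, correlation 0.77 and
per-gene log hazard 0.9, among 10 null pairs) and run the combined
cytokine/receptor analysis:

```r
library(cytoscreen)
fix <- file.path(tempdir(), "fx"); write_fixture_suite(fix, seed = 1)
d <- file.path(fix, "ligand_receptor")
res <- run_cyto_analysis(run_config(list(
  expression = file.path(d, "expression.tsv"),
  clinical   = file.path(d, "clinical.tsv"),
  pairing    = file.path(d, "pairing.tsv"),
  output_dir = file.path(tempdir(), "run1"))))
#> [input] 40 genes x 208 samples; 208 clinical rows
#> [normalize] 0 constant gene(s) dropped
#> [screen] tested 22/22 panel genes on 208 samples (OS, cox test)
#> [combined] top pair: IL1B / OSM (score 1.5)
#> [dual_km] both-high n=74 median=2.56; both-low n=87 median=16.7; logrank p=9.72e-23

head(as.data.frame(res$screen), 3)[, c("gene", "hazard_ratio", "p_value",
                                       "rank", "direction")]
#>    gene hazard_ratio      p_value rank direction
#> 1  IL1B     4.309229 2.429992e-18    1      poor
#> 2   OSM     3.852387 9.201313e-15    2      poor
#> 3 LIG09     1.188237 2.474241e-01    3      poor

head(res$combined, 3)
#>   ligand ligand_rank receptor_rank n_receptors combined_score order
#> 1   IL1B           1             2           1            1.5     1
#> 2  LIG02           7            10           1            8.5     2
#> 3  LIG06          12             5           1            8.5     3
```

Reading the output: the planted pair IL1B/OSM ranks 1st and 2nd in the
per-gene screen (hazard ratios ≈ 4 for above-mean expressors, both
`poor`-prognosis markers) and tops the combined rank with score 1.5 =
mean(1, 2). Patients concordantly high for both genes have a median
survival of 2.6 months against 16.7 months for the concordantly low
group (logrank p ≈ 1e-22) — the generator planted exactly this effect.
The output directory contains `screen.tsv`, `combined_rank.tsv`,
`top_pair_km.tsv`, a run log and the echoed config, all deterministic
under a fixed seed.

The second pipeline, `run_gene_program_analysis()`, chains Z-score
stratification on a target gene → Welch differential expression →
iterative Kaplan–Meier screening of the upregulated genes → gene-set
enrichment of the prognostic survivors. A thin command-line wrapper with
`simulate` / `cyto` / `gene-program` subcommands is installed at
`inst/scripts/cytoscreen.R`.

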