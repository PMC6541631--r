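Package: cytoscreen
Title: Prognostic Survival Screening of Cytokine and Receptor Expression
    in Tumor Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Survival-based screening of gene-expression biomarkers in
    tumor cohorts. Implements Kaplan-Meier estimation, the two-group
    logrank test and binary-covariate Cox proportional-hazards fitting
    from first principles; mean-dichotomized per-gene survival screens
    with a combined ligand-receptor prognostic rank score; iterative
    Kaplan-Meier filtering of gene lists; Z-score and copy-number
    zygosity patient stratification; genome-wide index-gene Pearson
    correlation ranking; and hypergeometric gene-set enrichment.
    Includes a seeded synthetic-cohort generator with planted
    proportional-hazards effects so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
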