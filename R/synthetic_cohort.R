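#' Configuration for a synthetic survival cohort
#'
#' Full generative specification of a TCGA-like tumor cohort with known
#' ground truth: per-gene standard-normal expression with optional planted
#' correlated ligand-receptor blocks, exponential (optionally Weibull)
#' survival whose hazard is multiplied by exp(beta) for each planted gene's
#' above-mean expressors, copy-number states with their own log-hazard
#' terms, and right censoring by an administrative horizon plus independent
#' exponential dropout.
#'
#' Hazard effects act on the dichotomized above-mean indicator (not the
#' continuous Z value), so exp(beta) is exactly the estimand of the
#' high-vs-low Cox fit used in screening.
#'
#' @param n_samples Cohort size (default 208, a typical GBM cohort).
#' @param n_genes Total genes including planted ones.
#' @param planted_pairs List of `list(ligand=, receptor=, rho=, beta=)`:
#'   ligand and receptor expression drawn bivariate normal with correlation
#'   `rho` in (-1, 1); each gene's above-mean indicator adds `beta` to the
#'   log hazard.
#' @param planted_genes List of `list(gene=, beta=)` single prognostic
#'   genes.
#' @param baseline_hazard Events per month for the reference patient
#'   (default 0.05/month, i.e. a ~14-month baseline median, typical of
#'   glioblastoma overall survival).
#' @param horizon_months Administrative censoring horizon (default 60;
#'   `Inf` disables it).
#' @param dropout_rate Rate of independent exponential dropout censoring
#'   (default 0.01/month; 0 disables it).
#' @param dfs_hazard_multiplier Hazard multiplier for the disease-free
#'   endpoint relative to overall survival (default 1.5: progression
#'   precedes death).
#' @param copy_number List of `list(gene=, probs=, log_hr=)`: `probs` are
#'   the five state probabilities over calls -2..2 (must sum to 1),
#'   `log_hr` the five per-state log-hazard terms (diploid conventionally
#'   0). Genes not listed are diploid throughout.
#' @param weibull_shape Weibull shape for the baseline hazard (default 1 =
#'   exponential, giving closed-form medians).
#' @param round_months Round observed times to whole months (default
#'   `FALSE`); useful for exercising tie handling.
#' @param seed Integer RNG seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A validated list of class `SyntheticCohortConfig`.
#' @export
cohort_config <- function(n_samples = 208, n_genes = 100,
                          planted_pairs = list(), planted_genes = list(),
                          baseline_hazard = 0.05, horizon_months = 60,
                          dropout_rate = 0.01, dfs_hazard_multiplier = 1.5,
                          copy_number = list(), weibull_shape = 1,
                          round_months = FALSE, seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, baseline_hazard > 0,
            horizon_months > 0, dropout_rate >= 0,
            dfs_hazard_multiplier > 0, weibull_shape > 0)
  for (pp in planted_pairs) {
    if (!all(c("ligand", "receptor", "rho", "beta") %in% names(pp)))
      stop("planted pair needs ligand, receptor, rho, beta")
    if (abs(pp$rho) >= 1) stop("pair correlation rho must lie in (-1, 1)")
  }
  for (pg in planted_genes)
    if (!all(c("gene", "beta") %in% names(pg)))
      stop("planted gene needs gene, beta")
  for (cn in copy_number) {
    if (!all(c("gene", "probs", "log_hr") %in% names(cn)))
      stop("copy-number entry needs gene, probs, log_hr")
    if (length(cn$probs) != 5 || abs(sum(cn$probs) - 1) > 1e-9)
      stop("copy-number state probabilities must be 5 values summing to 1")
    if (length(cn$log_hr) != 5)
      stop("copy-number log_hr must give 5 per-state values")
  }
  planted_names <- c(
    unlist(lapply(planted_pairs, function(p) c(p$ligand, p$receptor))),
    vapply(planted_genes, `[[`, "", "gene"))
  if (anyDuplicated(planted_names))
    stop("duplicate planted gene name(s): ",
         paste(unique(planted_names[duplicated(planted_names)]),
               collapse = ", "))
  if (length(planted_names) > n_genes)
    stop("n_genes smaller than the number of planted genes")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 planted_pairs = planted_pairs,
                 planted_genes = planted_genes,
                 baseline_hazard = baseline_hazard,
                 horizon_months = horizon_months,
                 dropout_rate = dropout_rate,
                 dfs_hazard_multiplier = dfs_hazard_multiplier,
                 copy_number = copy_number,
                 weibull_shape = weibull_shape,
                 round_months = isTRUE(round_months),
                 seed = as.integer(seed)),
            class = "SyntheticCohortConfig")
}

# inverse-transform Weibull PH draw: H(t) = lambda * t^shape * exp(lp)
draw_event_times <- function(n, lambda, shape, lp) {
  u <- stats::runif(n)
  (-log(u) / (lambda * exp(lp)))^(1 / shape)
}

#' Simulate a synthetic cohort
#'
#' Draws expression, survival and copy-number data according to a
#' [cohort_config()]. All randomness flows from the config's single seed;
#' the same config yields a bit-identical cohort.
#'
#' @param config A `SyntheticCohortConfig`.
#' @return A list with `expr` (raw `ExpressionMatrix`), `clinical`
#'   (`ClinicalTable` with OS and DFS), `cn` (`CopyNumberTable`), and
#'   `truth` (list echoing every planted effect plus the config).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "SyntheticCohortConfig"))
    stop("'config' must come from cohort_config()")
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  n <- config$n_samples
  planted_names <- c(
    unlist(lapply(config$planted_pairs,
                  function(p) c(p$ligand, p$receptor))),
    vapply(config$planted_genes, `[[`, "", "gene"))
  cn_names <- vapply(config$copy_number, `[[`, "", "gene")
  planted_names <- unique(c(planted_names, cn_names))
  n_filler <- config$n_genes - length(planted_names)
  if (n_filler < 0) stop("n_genes smaller than the number of named genes")
  genes <- c(planted_names,
             if (n_filler > 0) sprintf("G%04d", seq_len(n_filler)))
  samples <- sprintf("S%04d", seq_len(n))
  expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                 dimnames = list(genes, samples))
  for (pp in config$planted_pairs) {
    z1 <- stats::rnorm(n)
    z2 <- pp$rho * z1 + sqrt(1 - pp$rho^2) * stats::rnorm(n)
    expr[pp$ligand, ] <- z1
    expr[pp$receptor, ] <- z2
  }
  # linear predictor on the dichotomized above-mean indicators
  lp <- numeric(n)
  for (pp in config$planted_pairs) {
    lp <- lp + pp$beta * (expr[pp$ligand, ] > mean(expr[pp$ligand, ]))
    lp <- lp + pp$beta * (expr[pp$receptor, ] > mean(expr[pp$receptor, ]))
  }
  for (pg in config$planted_genes)
    lp <- lp + pg$beta * (expr[pg$gene, ] > mean(expr[pg$gene, ]))
  cn_calls <- matrix(0L, config$n_genes, n,
                     dimnames = list(genes, samples))
  for (cne in config$copy_number) {
    states <- sample((-2):2, n, replace = TRUE, prob = cne$probs)
    cn_calls[cne$gene, ] <- states
    lp <- lp + cne$log_hr[states + 3L]
  }
  censor_draw <- function() {
    cmin <- rep(config$horizon_months, n)
    if (config$dropout_rate > 0)
      cmin <- pmin(cmin, stats::rexp(n, config$dropout_rate))
    cmin
  }
  t_os <- draw_event_times(n, config$baseline_hazard, config$weibull_shape,
                           lp)
  c_os <- censor_draw()
  t_dfs <- draw_event_times(
    n, config$baseline_hazard * config$dfs_hazard_multiplier,
    config$weibull_shape, lp)
  c_dfs <- censor_draw()
  os_months <- pmin(t_os, c_os)
  dfs_months <- pmin(t_dfs, c_dfs)
  if (config$round_months) {
    os_months <- round(os_months)
    dfs_months <- round(dfs_months)
  }
  clin <- clinical_table(samples, os_months, as.integer(t_os <= c_os),
                         dfs_months = dfs_months,
                         dfs_event = as.integer(t_dfs <= c_dfs))
  list(expr = expression_matrix(expr, normalized = FALSE),
       clinical = clin,
       cn = copy_number_table(cn_calls),
       truth = list(planted_pairs = config$planted_pairs,
                    planted_genes = config$planted_genes,
                    copy_number = config$copy_number,
                    config = config))
}

write_truth <- function(truth, path) {
  cfg <- truth$config
  lines <- c(
    sprintf("n_samples=%d", cfg$n_samples),
    sprintf("n_genes=%d", cfg$n_genes),
    sprintf("baseline_hazard=%g", cfg$baseline_hazard),
    sprintf("horizon_months=%g", cfg$horizon_months),
    sprintf("dropout_rate=%g", cfg$dropout_rate),
    sprintf("dfs_hazard_multiplier=%g", cfg$dfs_hazard_multiplier),
    sprintf("weibull_shape=%g", cfg$weibull_shape),
    sprintf("seed=%d", cfg$seed),
    sprintf("n_planted_pairs=%d", length(cfg$planted_pairs)),
    sprintf("n_planted_genes=%d", length(cfg$planted_genes)))
  for (pp in cfg$planted_pairs)
    lines <- c(lines, sprintf("planted_pair=%s,%s,rho=%g,beta=%g",
                              pp$ligand, pp$receptor, pp$rho, pp$beta))
  for (pg in cfg$planted_genes)
    lines <- c(lines, sprintf("planted_gene=%s,beta=%g", pg$gene, pg$beta))
  for (cne in cfg$copy_number)
    lines <- c(lines, sprintf("copy_number=%s,probs=%s,log_hr=%s", cne$gene,
                              paste(cne$probs, collapse = ";"),
                              paste(cne$log_hr, collapse = ";")))
  writeLines(lines, path)
  invisible(path)
}

#' Write the standard synthetic fixture family
#'
#' Emits four small deterministic cohorts, each in its own subdirectory
#' with `expression.tsv`, `clinical.tsv`, `copy_number.tsv` and a
#' `truth.txt` record (plus `pairing.tsv` where relevant):
#' \describe{
#'   \item{null}{no planted effects — survival independent of every gene.}
#'   \item{single_gene}{one harmful gene `PLANT1` with log hazard 1.2 for
#'     above-mean expressors.}
#'   \item{ligand_receptor}{one correlated prognostic pair `IL1B`/`OSM`
#'     (rho 0.77, beta 0.9 per gene) among 10 null ligand-receptor pairs,
#'     with the pairing map.}
#'   \item{hetloss80}{a gene `SIRT1` with heterozygous loss in 80% of
#'     tumors carrying an extra log hazard of 1.}
#' }
#'
#' @param directory Output directory (created if absent).
#' @param seed Base RNG seed; each fixture derives its own fixed offset.
#' @return Invisibly, a named character vector of the fixture directories.
#' @export
write_fixture_suite <- function(directory, seed = 1L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  null_pairs <- lapply(1:10, function(i)
    list(ligand = sprintf("LIG%02d", i), receptor = sprintf("REC%02d", i),
         rho = 0.3, beta = 0))
  configs <- list(
    null = cohort_config(n_samples = 208, n_genes = 50, seed = seed),
    single_gene = cohort_config(
      n_samples = 208, n_genes = 50,
      planted_genes = list(list(gene = "PLANT1", beta = 1.2)),
      seed = seed + 1L),
    ligand_receptor = cohort_config(
      n_samples = 208, n_genes = 40,
      planted_pairs = c(list(list(ligand = "IL1B", receptor = "OSM",
                                  rho = 0.77, beta = 0.9)), null_pairs),
      seed = seed + 2L),
    hetloss80 = cohort_config(
      n_samples = 208, n_genes = 50,
      copy_number = list(list(gene = "SIRT1",
                              probs = c(0, 0.8, 0.2, 0, 0),
                              log_hr = c(0, 1, 0, 0, 0))),
      seed = seed + 3L))
  dirs <- character(0)
  for (nm in names(configs)) {
    d <- file.path(directory, nm)
    dir.create(d, showWarnings = FALSE)
    cohort <- simulate_cohort(configs[[nm]])
    write_expression(cohort$expr, file.path(d, "expression.tsv"))
    write_clinical(cohort$clinical, file.path(d, "clinical.tsv"))
    write_copy_number(cohort$cn, file.path(d, "copy_number.tsv"))
    write_truth(cohort$truth, file.path(d, "truth.txt"))
    if (nm == "ligand_receptor") {
      pm <- lapply(configs[[nm]]$planted_pairs, `[[`, "receptor")
      names(pm) <- vapply(configs[[nm]]$planted_pairs, `[[`, "", "ligand")
      write_pairing(pairing_map(pm), file.path(d, "pairing.tsv"))
    }
    dirs[nm] <- d
  }
  invisible(dirs)
}
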