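#' Dichotomize expression values at their mean
#'
#' Splits samples into high/low expressors at the mean of the non-missing
#' values: `high` iff value > mean, `low` otherwise (a value exactly at the
#' mean goes to `low`). Missing values stay missing (excluded downstream).
#'
#' @param values Numeric vector (one gene across samples).
#' @return Character vector of `"high"`/`"low"`/`NA`, same length and names
#'   as `values`.
#' @examples
#' dichotomize_mean(c(1, 2, 3))  # "low" "low" "high"
#' @export
dichotomize_mean <- function(values) {
  usable <- !is.na(values)
  if (sum(usable) < 2L)
    stop("dichotomize_mean needs at least 2 non-missing values")
  m <- mean(values[usable])
  out <- rep(NA_character_, length(values))
  out[usable] <- ifelse(values[usable] > m, "high", "low")
  names(out) <- names(values)
  out
}

# Two-level factor with "low" as reference so hazard ratios read high vs low.
high_low_factor <- function(labels) factor(labels, levels = c("low", "high"))

#' Per-gene survival screen over a gene list
#'
#' For each gene: dichotomize samples at the mean expression, then test the
#' high-vs-low survival difference. Both the Cox Wald p (with hazard ratio)
#' and the logrank p are computed; `test` selects which drives the ranking.
#' Ranks are assigned by ascending ranking p-value with average-rank ties;
#' Benjamini-Hochberg q-values are added across the testable genes. The
#' `direction` call is `"poor"` when the high-expressor hazard ratio exceeds
#' 1 (high expression marks poor prognosis), `"good"` otherwise; it is left
#' `NA` when the Cox fit did not converge.
#'
#' @param expr A Z-score normalized `ExpressionMatrix`.
#' @param clinical A `ClinicalTable` (sample ids intersected with `expr`).
#' @param gene_list Genes to screen (default: all genes in `expr`). Genes
#'   absent from the matrix are reported in the `missing_genes` attribute
#'   and skipped.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param test `"cox"` (default) or `"logrank"`: which p-value ranks genes.
#' @param alpha Significance threshold for the `significant` flag.
#' @param ties Tie handling for the Cox fit.
#' @return A data.frame of class `ScreenResult` with columns `gene`,
#'   `n_high`, `n_low`, `hazard_ratio`, `cox_p`, `logrank_p`, `p_value`
#'   (the ranking test), `q_value`, `rank`, `direction`, `significant`,
#'   `converged`. Attributes: `endpoint`, `test`, `alpha`, `missing_genes`,
#'   `untestable` (named character vector of reasons), `n_samples`.
#' @export
screen_genes <- function(expr, clinical, gene_list = NULL,
                         endpoint = c("OS", "DFS"),
                         test = c("cox", "logrank"),
                         alpha = 0.05, ties = "efron") {
  endpoint <- match.arg(endpoint)
  test <- match.arg(test)
  if (!is_normalized(expr))
    stop("screen_genes requires Z-score normalized expression")
  if (is.null(gene_list)) gene_list <- rownames(expr)
  missing_genes <- setdiff(gene_list, rownames(expr))
  gene_list <- gene_list[gene_list %in% rownames(expr)]
  al <- align_cohort(expr, clinical)
  ep <- endpoint_columns(al$clinical, endpoint)
  ex <- unclass(al$expr)[, ep$sample_id, drop = FALSE]
  untestable <- character(0)
  rows <- vector("list", length(gene_list))
  for (i in seq_along(gene_list)) {
    gene <- gene_list[i]
    v <- ex[gene, ]
    lab <- tryCatch(dichotomize_mean(v), error = function(e) NULL)
    if (is.null(lab)) {
      untestable[gene] <- "dichotomization failed (<2 usable values)"
      next
    }
    ok <- !is.na(lab)
    if (length(unique(lab[ok])) < 2L) {
      untestable[gene] <- "all samples on one side of the mean"
      next
    }
    cox <- cox_fit_binary(ep$time[ok], ep$event[ok],
                          high_low_factor(lab[ok]), ties = ties)
    lr <- suppressWarnings(
      logrank_test(ep$time[ok], ep$event[ok], high_low_factor(lab[ok])))
    rows[[i]] <- data.frame(
      gene = gene, n_high = sum(lab[ok] == "high"),
      n_low = sum(lab[ok] == "low"),
      hazard_ratio = cox$hazard_ratio, cox_p = cox$p_value,
      logrank_p = lr$p_value, converged = cox$converged,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene = character(0), n_high = integer(0),
                      n_low = integer(0), hazard_ratio = numeric(0),
                      cox_p = numeric(0), logrank_p = numeric(0),
                      converged = logical(0), stringsAsFactors = FALSE)
  res$p_value <- if (test == "cox") res$cox_p else res$logrank_p
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$rank <- rank(res$p_value, ties.method = "average")
  res$direction <- ifelse(res$converged,
                          ifelse(res$hazard_ratio > 1, "poor", "good"),
                          NA_character_)
  res$significant <- res$p_value < alpha
  res <- res[order(res$rank), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, endpoint = endpoint, test = test, alpha = alpha,
            missing_genes = missing_genes, untestable = untestable,
            n_samples = length(ep$time),
            class = c("ScreenResult", "data.frame"))
}

#' Write a screen result as TSV
#' @param x A `ScreenResult`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed comment lines written first.
#' @export
write_screen <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  cols <- c("gene", "n_high", "n_low", "hazard_ratio", "p_value", "q_value",
            "rank", "direction")
  utils::write.table(as.data.frame(x)[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

rank_aggregate <- function(ranks, rule) {
  switch(rule, mean = mean(ranks), sum = sum(ranks), best = min(ranks))
}

#' Combined ligand-receptor prognostic rank score
#'
#' Combines each ligand's screen rank with the rank(s) of its mapped
#' receptor(s) into one prognostic score per ligand signaling axis. For a
#' ligand with several screened receptors the receptor ranks are first
#' aggregated by the same rule; the combined score then aggregates the
#' ligand rank with the aggregated receptor rank. Final ordering is
#' ascending by combined score with a deterministic tie-break on ligand id.
#'
#' @param screen A `ScreenResult` covering both ligands and receptors.
#' @param pairing A `PairingMap`.
#' @param aggregation `"mean"` (default), `"sum"` or `"best"` (minimum).
#' @return A data.frame of class `CombinedRankResult`: `ligand`,
#'   `ligand_rank`, `receptor_rank`, `n_receptors`, `combined_score`,
#'   `order` (1 = best). Ligands with no screened receptor are listed in
#'   the `excluded` attribute.
#' @export
combined_rank <- function(screen, pairing,
                          aggregation = c("mean", "sum", "best")) {
  aggregation <- match.arg(aggregation)
  ranks <- stats::setNames(screen$rank, screen$gene)
  excluded <- character(0)
  rows <- list()
  for (lig in names(pairing)) {
    recs <- intersect(pairing[[lig]], names(ranks))
    if (!(lig %in% names(ranks)) || !length(recs)) {
      excluded[lig] <- if (!(lig %in% names(ranks)))
        "ligand not screened" else "no screened receptor"
      next
    }
    rrank <- rank_aggregate(unname(ranks[recs]), aggregation)
    score <- rank_aggregate(c(unname(ranks[lig]), rrank), aggregation)
    rows[[lig]] <- data.frame(ligand = lig, ligand_rank = unname(ranks[lig]),
                              receptor_rank = rrank,
                              n_receptors = length(recs),
                              combined_score = score,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    stop("no ligand with both itself and a receptor in the screen")
  res <- res[order(res$combined_score, res$ligand), , drop = FALSE]
  res$order <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, aggregation = aggregation, excluded = excluded,
            class = c("CombinedRankResult", "data.frame"))
}

#' Concordant dual-marker groups
#'
#' Dichotomizes two genes at their means and keeps only patients concordant
#' for both: both-high vs both-low. Discordant patients are excluded; the
#' two concordant groups feed a standard two-group survival comparison.
#'
#' @param expr An `ExpressionMatrix`.
#' @param gene_a,gene_b Gene identifiers present in `expr`.
#' @return Named character vector over samples: `"high"` (both high),
#'   `"low"` (both low) or `NA` (discordant or missing), with attribute
#'   `n_excluded`.
#' @export
dual_marker_groups <- function(expr, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(expr)) stop("gene not in expression matrix: ", g)
  la <- dichotomize_mean(unclass(expr)[gene_a, ])
  lb <- dichotomize_mean(unclass(expr)[gene_b, ])
  out <- rep(NA_character_, ncol(expr))
  names(out) <- colnames(expr)
  conc <- !is.na(la) & !is.na(lb) & la == lb
  out[conc] <- la[conc]
  if (!any(out == "high", na.rm = TRUE))
    stop("empty concordant group: both-high")
  if (!any(out == "low", na.rm = TRUE))
    stop("empty concordant group: both-low")
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' Z-score threshold stratification
#'
#' Classifies patients as high expressors (z above `hi_threshold`), low
#' expressors (z below `lo_threshold`) or excluded (the band in between).
#' Defaults follow the common 0.25 / -0.25 convention for cohort Z-scores.
#'
#' @param expr A Z-score normalized `ExpressionMatrix`.
#' @param gene Gene identifier.
#' @param hi_threshold,lo_threshold Strict thresholds; `hi_threshold` must
#'   exceed `lo_threshold` so the excluded band is well-defined (for an
#'   empty band use [dichotomize_mean()] instead).
#' @return Named character vector of `"high"`/`"low"`/`NA` with attribute
#'   `n_excluded`.
#' @export
stratify_zscore <- function(expr, gene, hi_threshold = 0.25,
                            lo_threshold = -0.25) {
  if (!is_normalized(expr))
    stop("stratify_zscore requires Z-score normalized expression")
  if (hi_threshold <= lo_threshold)
    stop("hi_threshold must be strictly greater than lo_threshold")
  if (!gene %in% rownames(expr))
    stop("gene not in expression matrix: ", gene)
  z <- unclass(expr)[gene, ]
  out <- rep(NA_character_, length(z))
  names(out) <- colnames(expr)
  out[!is.na(z) & z > hi_threshold] <- "high"
  out[!is.na(z) & z < lo_threshold] <- "low"
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' Copy-number zygosity groups
#'
#' Maps GISTIC-style integer calls to zygosity labels and reports group
#' frequencies (e.g. the fraction of tumors with heterozygous loss of a
#' gene).
#'
#' @param cn A `CopyNumberTable`.
#' @param gene Gene identifier present in the table.
#' @return Named factor over samples with levels `deep_deletion`,
#'   `hetloss`, `diploid`, `gain`, `amplification`; attribute `frequencies`
#'   holds the per-level fraction among non-missing calls.
#' @export
zygosity_groups <- function(cn, gene) {
  if (!gene %in% rownames(cn)) stop("gene not in copy-number table: ", gene)
  codes <- unclass(cn)[gene, ]
  lev <- c("deep_deletion", "hetloss", "diploid", "gain", "amplification")
  lab <- factor(lev[codes + 3L], levels = lev)
  names(lab) <- colnames(cn)
  freq <- table(lab) / sum(!is.na(lab))
  attr(lab, "frequencies") <- as.numeric(freq)
  names(attr(lab, "frequencies")) <- lev
  lab
}

#' Joint two-gene Z-score stratification
#'
#' Stratifies both genes by [stratify_zscore()] and crosses the calls into
#' four cells (`high.high`, `high.low`, `low.high`, `low.low`; gene A
#' first). Optionally collapses a configured pair of cell sets into a
#' two-group comparison, e.g. A-high/B-low vs everything else, or
#' A-high/B-low vs A-low/B-high.
#'
#' @inheritParams stratify_zscore
#' @param gene_a,gene_b Gene identifiers.
#' @param compare Optional list with elements `group1` and `group2`, each a
#'   character vector of cell names (`"rest"` in `group2` means all
#'   stratified patients not in `group1`). If given, the return value is a
#'   two-level factor `group1`/`group2`.
#' @return Named character vector of four-way cells (or two-group factor),
#'   `NA` for patients excluded for either gene; attribute `n_excluded`.
#' @export
joint_stratify <- function(expr, gene_a, gene_b, hi_threshold = 0.25,
                           lo_threshold = -0.25, compare = NULL) {
  la <- stratify_zscore(expr, gene_a, hi_threshold, lo_threshold)
  lb <- stratify_zscore(expr, gene_b, hi_threshold, lo_threshold)
  cells <- ifelse(is.na(la) | is.na(lb), NA_character_,
                  paste(la, lb, sep = "."))
  names(cells) <- colnames(expr)
  if (is.null(compare)) {
    attr(cells, "n_excluded") <- sum(is.na(cells))
    return(cells)
  }
  valid <- c("high.high", "high.low", "low.high", "low.low")
  g1 <- compare$group1
  g2 <- compare$group2
  if (!all(g1 %in% valid)) stop("unknown cell in compare$group1")
  if (!all(g2 %in% c(valid, "rest"))) stop("unknown cell in compare$group2")
  if ("rest" %in% g2) g2 <- setdiff(valid, g1)
  out <- rep(NA_character_, length(cells))
  out[cells %in% g1] <- "group1"
  out[cells %in% g2] <- "group2"
  if (!any(out == "group1", na.rm = TRUE))
    stop("selected cells empty: group1 (", paste(g1, collapse = ","), ")")
  if (!any(out == "group2", na.rm = TRUE))
    stop("selected cells empty: group2 (", paste(g2, collapse = ","), ")")
  out <- factor(out, levels = c("group1", "group2"))
  names(out) <- colnames(expr)
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' Iterative Kaplan-Meier screen of a gene list
#'
#' Runs the per-gene survival screen over a gene list and keeps the genes
#' whose ranking p-value falls below `alpha`, each labeled as a marker of
#' poor prognosis (high-expressor hazard ratio > 1) or good prognosis.
#' The poor/good split among survivors is reported so statements like
#' "most prognostic genes in this program mark poor outcome" can be made
#' quantitatively.
#'
#' @inheritParams screen_genes
#' @param alpha Retention threshold on the ranking p-value.
#' @return A `ScreenResult` restricted to significant genes with non-NA
#'   direction, with extra attributes `poor_fraction`, `n_significant`,
#'   `n_tested`.
#' @export
iterative_km <- function(expr, clinical, gene_list = NULL,
                         endpoint = c("OS", "DFS"),
                         test = c("cox", "logrank"),
                         alpha = 0.05, ties = "efron") {
  s <- screen_genes(expr, clinical, gene_list, endpoint = endpoint,
                    test = test, alpha = alpha, ties = ties)
  keep <- s$p_value < alpha & !is.na(s$direction)
  res <- s[keep, , drop = FALSE]
  rownames(res) <- NULL
  for (a in c("endpoint", "test", "alpha", "missing_genes", "untestable",
              "n_samples"))
    attr(res, a) <- attr(s, a)
  attr(res, "n_tested") <- nrow(s)
  attr(res, "n_significant") <- nrow(res)
  attr(res, "poor_fraction") <-
    if (nrow(res)) mean(res$direction == "poor") else NA_real_
  class(res) <- c("ScreenResult", "data.frame")
  res
}
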