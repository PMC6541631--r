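#' Genome-wide Pearson correlation ranking against an index gene
#'
#' Correlates every gene in the matrix with a chosen index gene
#' (product-moment r over pairwise-complete samples) and ranks genes by
#' descending r. The p-value uses the exact t transform
#' t = r sqrt((n - 2) / (1 - r^2)) against a t distribution with n - 2
#' degrees of freedom, two-sided. The index gene itself is excluded; genes
#' with fewer than 3 complete pairs are excluded and reported.
#'
#' @param expr An `ExpressionMatrix` (raw or normalized; r is
#'   scale-invariant).
#' @param index_gene Gene identifier present in `expr`.
#' @return A data.frame of class `CorrelationRank` with columns `gene`,
#'   `r`, `p_value`, `n`, `rank` (1 = most positively correlated), ordered
#'   by rank; attribute `excluded` lists untestable genes.
#' @export
pearson_rank <- function(expr, index_gene) {
  if (!index_gene %in% rownames(expr))
    stop("index gene not in expression matrix: ", index_gene)
  v <- unclass(expr)
  idx <- v[index_gene, ]
  others <- setdiff(rownames(v), index_gene)
  n_pair <- vapply(others, function(g)
    sum(!is.na(idx) & !is.na(v[g, ])), integer(1))
  excluded <- others[n_pair < 3L]
  keep <- others[n_pair >= 3L]
  r <- vapply(keep, function(g)
    stats::cor(idx, v[g, ], use = "pairwise.complete.obs"), numeric(1))
  n <- n_pair[keep]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  res <- data.frame(gene = keep, r = unname(r), p_value = unname(p),
                    n = unname(n), stringsAsFactors = FALSE)
  res$rank <- rank(-res$r, ties.method = "average")
  res <- res[order(res$rank), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, index_gene = index_gene, excluded = excluded,
            class = c("CorrelationRank", "data.frame"))
}

#' Two-group differential expression (Welch test)
#'
#' Per-gene comparison of high-expressor vs low-expressor patients by a
#' Welch two-sample t-test on the expression values, with
#' Benjamini-Hochberg q-values across genes. Deliberately a plain
#' unmoderated test: each gene stands on its own variance estimate.
#'
#' @param expr An `ExpressionMatrix`.
#' @param high_samples,low_samples Disjoint sample-id vectors.
#' @param q_threshold Threshold for the `upregulated_in_high` call.
#' @return A data.frame of class `DeResult` with columns `gene`,
#'   `mean_high`, `mean_low`, `difference` (high - low), `t_stat`,
#'   `p_value`, `q_value`, `n_high`, `n_low`, `upregulated_in_high`;
#'   attribute `untestable` names genes with fewer than 2 usable values in
#'   either group.
#' @export
two_group_de <- function(expr, high_samples, low_samples,
                         q_threshold = 0.05) {
  if (length(intersect(high_samples, low_samples)))
    stop("high and low sample sets overlap")
  v <- unclass(expr)
  hi <- v[, intersect(high_samples, colnames(v)), drop = FALSE]
  lo <- v[, intersect(low_samples, colnames(v)), drop = FALSE]
  if (!ncol(hi) || !ncol(lo)) stop("empty sample group")
  n1 <- rowSums(!is.na(hi))
  n2 <- rowSums(!is.na(lo))
  testable <- n1 >= 2 & n2 >= 2
  untestable <- rownames(v)[!testable]
  m1 <- rowMeans(hi, na.rm = TRUE)
  m2 <- rowMeans(lo, na.rm = TRUE)
  s1 <- apply(hi, 1, stats::var, na.rm = TRUE)
  s2 <- apply(lo, 1, stats::var, na.rm = TRUE)
  diff <- m1 - m2
  se2 <- s1 / n1 + s2 / n2
  df <- se2^2 / (s1^2 / (n1^2 * (n1 - 1)) + s2^2 / (n2^2 * (n2 - 1)))
  tt <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df = df)
  # zero-variance degenerate rows: identical groups get p = 1, a real
  # difference with no within-group spread gets p -> 0
  zero <- !is.na(se2) & se2 == 0
  p[zero & diff == 0] <- 1
  tt[zero & diff == 0] <- 0
  p[zero & diff != 0] <- 0
  res <- data.frame(gene = rownames(v)[testable],
                    mean_high = unname(m1[testable]),
                    mean_low = unname(m2[testable]),
                    difference = unname(diff[testable]),
                    t_stat = unname(tt[testable]),
                    p_value = unname(p[testable]),
                    n_high = unname(n1[testable]),
                    n_low = unname(n2[testable]),
                    stringsAsFactors = FALSE)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$upregulated_in_high <- res$difference > 0 & res$q_value < q_threshold
  structure(res, untestable = untestable, q_threshold = q_threshold,
            class = c("DeResult", "data.frame"))
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation of a target gene list within
#' a universe by the one-sided hypergeometric tail
#' p = P(overlap >= observed), with Benjamini-Hochberg q-values across the
#' library. Gene sets are intersected with the universe first; sets
#' disjoint from the universe are skipped.
#'
#' @param target_genes Character vector of hit genes (must lie within
#'   `universe`; genes outside it are dropped with a message).
#' @param universe Character vector: the background gene population,
#'   typically all genes measured after QC.
#' @param library A `GeneSetLibrary`.
#' @return A data.frame of class `EnrichmentResult` with columns `set`,
#'   `overlap`, `set_size`, `target_size`, `universe_size`, `p_value`,
#'   `q_value`, `genes` (comma-joined overlap), ordered by p; attribute
#'   `skipped` lists sets disjoint from the universe.
#' @export
enrich_gene_sets <- function(target_genes, universe, library) {
  universe <- unique(universe)
  target_genes <- unique(target_genes)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(target_genes, universe)
  if (length(outside)) {
    message(length(outside), " target gene(s) outside the universe dropped")
    target_genes <- intersect(target_genes, universe)
  }
  if (!length(target_genes)) stop("empty target gene list")
  N <- length(universe)
  k <- length(target_genes)
  skipped <- character(0)
  rows <- list()
  for (nm in names(library)) {
    set <- intersect(library[[nm]], universe)
    if (!length(set)) {
      skipped <- c(skipped, nm)
      next
    }
    ov <- intersect(set, target_genes)
    m <- length(set)
    # P(X >= |ov|) for X ~ Hypergeometric(N, m, k)
    p <- stats::phyper(length(ov) - 1, m, N - m, k, lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, overlap = length(ov), set_size = m,
                             target_size = k, universe_size = N,
                             p_value = p,
                             genes = paste(sort(ov), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), target_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set),
             c("set", "overlap", "set_size", "target_size", "universe_size",
               "p_value", "q_value", "genes")]
  rownames(res) <- NULL
  structure(res, skipped = skipped,
            class = c("EnrichmentResult", "data.frame"))
}
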