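test_that("dichotomize_mean applies the ties-to-low rule and partitions", {
  expect_identical(unname(dichotomize_mean(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_identical(unname(dichotomize_mean(c(-1, 1))), c("low", "high"))
  expect_error(dichotomize_mean(c(1, NA)), "at least 2")
  set.seed(201)
  for (i in 1:20) {
    v <- rnorm(30)
    v[sample(30, 5)] <- NA
    lab <- dichotomize_mean(v)
    expect_identical(sum(lab == "high", na.rm = TRUE) +
                       sum(lab == "low", na.rm = TRUE),
                     sum(!is.na(v)))
    expect_identical(is.na(lab), is.na(v))
  }
})

test_that("screen_genes ranks a planted prognostic gene first (seed majority)", {
  hits <- 0L
  for (seed in 1:5) {
    cfg <- cohort_config(n_samples = 200, n_genes = 50,
                         planted_genes = list(list(gene = "PLANT1",
                                                   beta = 1.2)),
                         seed = seed)
    co <- simulate_cohort(cfg)
    s <- screen_genes(zscore_normalize(co$expr), co$clinical)
    if (s$gene[1] == "PLANT1") hits <- hits + 1L
    expect_identical(sort(s$rank), as.numeric(seq_len(nrow(s))))
    expect_equal(s$q_value, p.adjust(s$p_value, "BH"))
  }
  expect_gte(hits, 4L)
})

test_that("screen_genes output is invariant to gene order and reports gaps", {
  cfg <- cohort_config(n_samples = 120, n_genes = 20, seed = 3)
  co <- simulate_cohort(cfg)
  z <- zscore_normalize(co$expr)
  genes <- rownames(z)
  s1 <- screen_genes(z, co$clinical, genes)
  s2 <- screen_genes(z, co$clinical, rev(genes))
  m <- match(s1$gene, s2$gene)
  expect_equal(s1$p_value, s2$p_value[m])
  expect_equal(s1$rank, s2$rank[m])

  s3 <- screen_genes(z, co$clinical, c(genes[1:3], "NOT_A_GENE"))
  expect_identical(attr(s3, "missing_genes"), "NOT_A_GENE")
  expect_identical(nrow(s3), 3L)
})

test_that("untestable genes are excluded from ranking with a reason", {
  cfg <- cohort_config(n_samples = 80, n_genes = 10, seed = 4)
  co <- simulate_cohort(cfg)
  v <- unclass(co$expr)
  v["G0001", ] <- 7   # constant -> all-NA after normalization
  z <- zscore_normalize(expression_matrix(v))
  s <- screen_genes(z, co$clinical)
  expect_false("G0001" %in% s$gene)
  expect_match(attr(s, "untestable")[["G0001"]], "dichotomization")
  expect_identical(sort(s$rank), as.numeric(seq_len(nrow(s))))
})

test_that("combined_rank follows the declared aggregation arithmetic", {
  screen <- structure(
    data.frame(gene = c("L1", "R1", "L2", "R2a", "R2b"),
               rank = c(1, 3, 5, 2, 6),
               p_value = c(.001, .01, .5, .005, .6),
               stringsAsFactors = FALSE),
    class = c("ScreenResult", "data.frame"))
  pm <- pairing_map(list(L1 = "R1", L2 = c("R2a", "R2b")))
  cr <- combined_rank(screen, pm, "mean")
  expect_equal(cr$combined_score[cr$ligand == "L1"], 2)        # (1+3)/2
  expect_equal(cr$receptor_rank[cr$ligand == "L2"], 4)         # (2+6)/2
  expect_equal(cr$combined_score[cr$ligand == "L2"], 4.5)      # (5+4)/2
  expect_identical(cr$ligand[1], "L1")

  cr_sum <- combined_rank(screen, pm, "sum")
  expect_equal(cr_sum$combined_score[cr_sum$ligand == "L2"], 5 + 8)
  cr_best <- combined_rank(screen, pm, "best")
  expect_equal(cr_best$combined_score[cr_best$ligand == "L2"], 2)

  pm2 <- pairing_map(list(L1 = "R1", LX = "NOPE"))
  cr2 <- combined_rank(screen, pm2)
  expect_identical(names(attr(cr2, "excluded")), "LX")
})

test_that("combined_rank agrees with exhaustive recomputation", {
  set.seed(202)
  for (i in 1:20) {
    n_lig <- sample(3:8, 1)
    genes <- c(sprintf("L%02d", 1:n_lig), sprintf("R%02d", 1:(2 * n_lig)))
    p <- runif(length(genes))
    screen <- structure(
      data.frame(gene = genes, p_value = p,
                 rank = rank(p, ties.method = "average"),
                 stringsAsFactors = FALSE),
      class = c("ScreenResult", "data.frame"))
    pm <- pairing_map(stats::setNames(
      lapply(1:n_lig, function(j)
        sprintf("R%02d", sample(1:(2 * n_lig), sample(1:2, 1)))),
      sprintf("L%02d", 1:n_lig)))
    rule <- sample(c("mean", "sum", "best"), 1)
    agg <- switch(rule, mean = mean, sum = sum, best = min)
    cr <- combined_rank(screen, pm, rule)
    # brute recomputation straight from the per-gene rank table
    rk <- stats::setNames(screen$rank, screen$gene)
    for (row in seq_len(nrow(cr))) {
      lig <- cr$ligand[row]
      rr <- agg(unname(rk[unique(pm[[lig]])]))
      expect_equal(cr$receptor_rank[row], rr)
      expect_equal(cr$combined_score[row], agg(c(unname(rk[lig]), rr)))
    }
    expect_identical(cr$order,
                     seq_len(nrow(cr))[order(order(cr$combined_score,
                                                   cr$ligand))])
  }
})

test_that("dual_marker_groups keeps concordant patients only", {
  # A = (2, 2, -1, 0), mean 0.75 -> H H L L
  # B = (0, 2,  2, -2), mean 0.5  -> L H H L
  v <- gene_mat(2, 4, c(2, 0, 2, 2, -1, 2, 0, -2), genes = c("A", "B"))
  m <- expression_matrix(v)
  g <- dual_marker_groups(m, "A", "B")
  expect_identical(as.vector(g), c(NA, "high", NA, "low"))
  expect_identical(attr(g, "n_excluded"), 2L)

  # geneA == geneB degenerates to the single-gene split, no exclusions
  v2 <- gene_mat(2, 4, rep(c(1, 2, 3, 4), each = 2), genes = c("A", "B"))
  g2 <- dual_marker_groups(expression_matrix(v2), "A", "B")
  expect_identical(attr(g2, "n_excluded"), 0L)
  expect_identical(as.vector(g2), as.vector(dichotomize_mean(v2["A", ])))

  v3 <- gene_mat(2, 4, c(3, -3, 2, -2, 1, -1, 4, -4), genes = c("A", "B"))
  expect_error(dual_marker_groups(expression_matrix(v3), "A", "B"),
               "both-high|both-low")
})

test_that("concordant both-high patients of a planted pair fare worse", {
  cfg <- cohort_config(n_samples = 400, n_genes = 30,
                       planted_pairs = list(list(ligand = "IL1B",
                                                 receptor = "OSM",
                                                 rho = 0.77, beta = 0.9)),
                       seed = 5)
  co <- simulate_cohort(cfg)
  g <- dual_marker_groups(co$expr, "IL1B", "OSM")
  ep <- endpoint_columns(co$clinical, "OS")
  gg <- g[ep$sample_id]
  ok <- !is.na(gg)
  fit <- cox_fit_binary(ep$time[ok], ep$event[ok],
                        factor(gg[ok], levels = c("low", "high")))
  expect_gt(fit$hazard_ratio, 1)
  km_hi <- km_estimate(ep$time[ok & gg == "high"],
                       ep$event[ok & gg == "high"])
  km_lo <- km_estimate(ep$time[ok & gg == "low"],
                       ep$event[ok & gg == "low"])
  expect_lt(km_hi$median_survival, km_lo$median_survival)
})

test_that("stratify_zscore applies strict thresholds and the excluded band", {
  v <- gene_mat(1, 3, c(0.3, 0.0, -0.3), genes = "RELB")
  m <- as_normalized(v)
  lab <- stratify_zscore(m, "RELB")
  expect_identical(as.vector(lab), c("high", NA, "low"))
  expect_error(stratify_zscore(m, "RELB", 0, 0), "strictly")
  expect_error(stratify_zscore(expression_matrix(v), "RELB"), "normalized")

  set.seed(203)
  z <- gene_mat(1, 5000, rnorm(5000), genes = "RELB",
                samples = sprintf("s%04d", 1:5000))
  lab2 <- stratify_zscore(as_normalized(z), "RELB")
  frac_excl <- attr(lab2, "n_excluded") / 5000
  expected <- pnorm(0.25) - pnorm(-0.25)
  expect_lt(abs(frac_excl - expected), 3 * sqrt(expected * (1 - expected) / 5000) + 0.005)
})

test_that("zygosity_groups maps GISTIC codes and reports frequencies", {
  calls <- gene_mat(1, 4, c(0L, -1L, -1L, 0L), genes = "SIRT1")
  g <- zygosity_groups(copy_number_table(calls), "SIRT1")
  expect_identical(as.character(unname(g)),
                   c("diploid", "hetloss", "hetloss", "diploid"))
  expect_equal(attr(g, "frequencies")[["hetloss"]], 0.5)
  calls2 <- gene_mat(1, 2, c(2L, -2L), genes = "RELB")
  g2 <- zygosity_groups(copy_number_table(calls2), "RELB")
  expect_identical(as.character(unname(g2)),
                   c("amplification", "deep_deletion"))
  expect_error(zygosity_groups(copy_number_table(calls), "TP53"), "TP53")
})

test_that("joint_stratify crosses calls and honors cell selection", {
  set.seed(204)
  v <- gene_mat(2, 4000, rnorm(8000), genes = c("RELB", "SIRT1"),
                samples = sprintf("s%04d", 1:4000))
  m <- as_normalized(v)
  cells <- joint_stratify(m, "RELB", "SIRT1")
  p_hi <- 1 - pnorm(0.25)
  share <- mean(cells == "high.high", na.rm = TRUE) *
    mean(!is.na(cells))
  expect_lt(abs(share - p_hi^2), 0.03)

  # geneB == -geneA: the high.high cell must be empty
  v2 <- rbind(RELB = v[1, ], SIRT1 = -v[1, ])
  cells2 <- joint_stratify(as_normalized(v2), "RELB", "SIRT1")
  expect_false(any(cells2 == "high.high", na.rm = TRUE))
  expect_error(
    joint_stratify(as_normalized(v2), "RELB", "SIRT1",
                   compare = list(group1 = "high.high", group2 = "rest")),
    "empty")

  two <- joint_stratify(m, "RELB", "SIRT1",
                        compare = list(group1 = "high.low",
                                       group2 = "low.high"))
  expect_identical(levels(two), c("group1", "group2"))
  expect_identical(sum(!is.na(two)) + attr(two, "n_excluded"), 4000L)
  expect_identical(unname(table(two)[["group1"]]),
                   sum(cells == "high.low", na.rm = TRUE))
})

test_that("iterative_km filters at alpha and calls directions", {
  cfg <- cohort_config(n_samples = 200, n_genes = 40,
                       planted_genes = list(list(gene = "BAD1", beta = 1.3)),
                       seed = 6)
  co <- simulate_cohort(cfg)
  z <- zscore_normalize(co$expr)
  res <- iterative_km(z, co$clinical, alpha = 0.05)
  expect_true(all(res$p_value < 0.05))
  expect_true("BAD1" %in% res$gene)
  expect_identical(res$direction[res$gene == "BAD1"], "poor")

  all_back <- iterative_km(z, co$clinical, alpha = 1)
  expect_identical(nrow(all_back), attr(all_back, "n_tested"))

  # null cohort: roughly alpha of genes survive by chance
  n_false <- vapply(1:3, function(seed) {
    cn <- simulate_cohort(cohort_config(n_samples = 150, n_genes = 100,
                                        seed = 100 + seed))
    nrow(iterative_km(zscore_normalize(cn$expr), cn$clinical, alpha = 0.05))
  }, integer(1))
  expect_lt(mean(n_false), 15)   # E = 5 per 100 under the null
})
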