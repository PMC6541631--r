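#' Read a flat key=value run configuration
#'
#' One `key=value` pair per line; blank lines and `#` comments are ignored.
#' Values for known numeric keys are converted; everything else stays
#' character. Unknown keys are kept verbatim so configs can carry notes.
#'
#' @param path Path to the config file.
#' @param overrides Named list applied on top of the file values.
#' @return Named list of class `RunConfig`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE),
                   invert = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  cfg <- stats::setNames(lapply(kv, function(p) trimws(p[2])),
                         vapply(kv, function(p) trimws(p[1]), ""))
  cfg[names(overrides)] <- overrides
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of raw config values.
#' @export
run_config <- function(cfg) {
  num_keys <- c("alpha", "z_hi", "z_lo", "de_q_threshold", "seed")
  for (k in intersect(num_keys, names(cfg)))
    cfg[[k]] <- as.numeric(cfg[[k]])
  defaults <- list(endpoint = "OS", test = "cox", aggregation = "mean",
                   alpha = 0.05, z_hi = 0.25, z_lo = -0.25,
                   de_q_threshold = 0.05, dialect = "plain",
                   normalize = "true", output_dir = "cytoscreen_run")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("expression", "clinical", "pairing", "gene_sets", "gene_list"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config references missing file: ", k, " = ", cfg[[k]])
  structure(cfg, class = "RunConfig")
}

# Echo the config into the output directory and return its md5 hash.
echo_config <- function(cfg, out_dir) {
  keys <- sort(setdiff(names(cfg), "output_dir"))
  path <- file.path(out_dir, "config_used.txt")
  writeLines(sprintf("%s=%s", keys,
                     vapply(cfg[keys], function(v) paste(format(v), collapse = ","), "")),
             path)
  unname(tools::md5sum(path))
}

pipeline_header <- function(cfg_hash, n) {
  c(sprintf("cytoscreen %s",
            as.character(utils::packageVersion("cytoscreen"))),
    sprintf("config_hash=%s", cfg_hash),
    sprintf("n_samples=%d", n))
}

write_table_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_log <- function(con, stage, text) {
  line <- sprintf("[%s] %s", stage, text)
  message(line)
  writeLines(line, con)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the combined cytokine/receptor prognostic analysis
#'
#' End-to-end screen of a cytokine/receptor panel: read expression and
#' clinical tables, Z-score normalize, run the per-gene survival screen
#' over all panel genes (every ligand and receptor in the pairing map),
#' build the combined ligand-receptor rank table, and export the
#' dual-marker (both-high vs both-low) Kaplan-Meier comparison for the
#' top-ranked pair. All outputs are deterministic functions of the inputs
#' and config.
#'
#' @param config A `RunConfig` (or path to a key=value config file)
#'   with at least `expression`, `clinical`, `pairing` and `output_dir`.
#' @return Invisibly, a list with `screen`, `combined`, `top_pair` and the
#'   output directory.
#' @export
run_cyto_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "RunConfig")) config <- run_config(config)
  for (k in c("expression", "clinical", "pairing"))
    if (is.null(config[[k]])) stop("config key required: ", k)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- echo_config(config, out_dir)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))

  expr <- with_stage("read_expression",
                     read_expression(config$expression, config$dialect))
  clin <- with_stage("read_clinical", read_clinical(config$clinical))
  pairing <- with_stage("read_pairing", read_pairing(config$pairing))
  run_log(log_con, "input", sprintf("%d genes x %d samples; %d clinical rows",
                                    nrow(expr), ncol(expr), nrow(clin)))
  if (identical(config$normalize, "true")) {
    expr <- with_stage("normalize", zscore_normalize(expr))
    run_log(log_con, "normalize",
            sprintf("%d constant gene(s) dropped",
                    length(attr(expr, "constant_genes"))))
  }
  panel <- unique(c(names(pairing), unlist(pairing)))
  screen <- with_stage("screen", screen_genes(
    expr, clin, gene_list = panel, endpoint = config$endpoint,
    test = config$test, alpha = config$alpha))
  n_eff <- attr(screen, "n_samples")
  run_log(log_con, "screen",
          sprintf("tested %d/%d panel genes on %d samples (%s, %s test)",
                  nrow(screen), length(panel), n_eff, config$endpoint,
                  config$test))
  header <- pipeline_header(cfg_hash, n_eff)
  write_screen(screen, file.path(out_dir, "screen.tsv"),
               header_comment = header)
  combined <- with_stage("combined_rank",
                         combined_rank(screen, pairing, config$aggregation))
  write_table_with_header(as.data.frame(combined),
                          file.path(out_dir, "combined_rank.tsv"), header)
  top <- combined$ligand[1]
  top_rec <- pairing[[top]][1]
  run_log(log_con, "combined",
          sprintf("top pair: %s / %s (score %.3g)", top, top_rec,
                  combined$combined_score[1]))
  al <- align_cohort(expr, clin)
  groups <- with_stage("dual_marker",
                       dual_marker_groups(al$expr, top, top_rec))
  ep <- endpoint_columns(al$clinical, config$endpoint)
  g <- groups[ep$sample_id]
  ok <- !is.na(g)
  km_hi <- km_estimate(ep$time[ok & g == "high"], ep$event[ok & g == "high"])
  km_lo <- km_estimate(ep$time[ok & g == "low"], ep$event[ok & g == "low"])
  lr <- logrank_test(ep$time[ok], ep$event[ok], g[ok])
  run_log(log_con, "dual_km",
          sprintf("both-high n=%d median=%.3g; both-low n=%d median=%.3g; logrank p=%.3g",
                  km_hi$n, km_hi$median_survival, km_lo$n,
                  km_lo$median_survival, lr$p_value))
  km_df <- rbind(cbind(group = "both_high", km_table(km_hi)),
                 cbind(group = "both_low", km_table(km_lo)))
  write_table_with_header(km_df, file.path(out_dir, "top_pair_km.tsv"),
                          header)
  invisible(list(screen = screen, combined = combined,
                 top_pair = c(ligand = top, receptor = top_rec),
                 logrank = lr, output_dir = out_dir))
}

#' Run the gene-program prognostic analysis
#'
#' Mirrors the index-gene program workflow: stratify patients on a target
#' gene by Z-score thresholds, run the two-group differential-expression
#' test, collect the genes upregulated in the high expressors, screen a
#' gene list by iterative Kaplan-Meier filtering, and test the prognostic
#' survivors for gene-set enrichment against a GMT library.
#'
#' @param config A `RunConfig` (or path) with `expression`, `clinical`,
#'   `target_gene`, `output_dir`, and optionally `gene_sets` (GMT path)
#'   and `gene_list` (text file, one gene per line; default: the
#'   upregulated genes from the differential-expression stage).
#' @return Invisibly, a list with `de`, `upregulated`, `survivors`,
#'   `enrichment` and the output directory.
#' @export
run_gene_program_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "RunConfig")) config <- run_config(config)
  for (k in c("expression", "clinical", "target_gene"))
    if (is.null(config[[k]])) stop("config key required: ", k)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- echo_config(config, out_dir)
  log_con <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(log_con))

  expr <- with_stage("read_expression",
                     read_expression(config$expression, config$dialect))
  clin <- with_stage("read_clinical", read_clinical(config$clinical))
  if (identical(config$normalize, "true"))
    expr <- with_stage("normalize", zscore_normalize(expr))
  strata <- with_stage("stratify", stratify_zscore(
    expr, config$target_gene, config$z_hi, config$z_lo))
  hi <- names(strata)[!is.na(strata) & strata == "high"]
  lo <- names(strata)[!is.na(strata) & strata == "low"]
  run_log(log_con, "stratify",
          sprintf("%s: %d high, %d low, %d excluded", config$target_gene,
                  length(hi), length(lo), attr(strata, "n_excluded")))
  de <- with_stage("two_group_de",
                   two_group_de(expr, hi, lo,
                                q_threshold = config$de_q_threshold))
  up <- de$gene[de$upregulated_in_high]
  run_log(log_con, "de", sprintf("%d/%d genes upregulated in high at q<%g",
                                 length(up), nrow(de),
                                 config$de_q_threshold))
  header <- pipeline_header(cfg_hash, length(hi) + length(lo))
  write_table_with_header(as.data.frame(de),
                          file.path(out_dir, "differential_expression.tsv"),
                          header)
  writeLines(up, file.path(out_dir, "upregulated_genes.txt"))
  gene_list <- if (!is.null(config$gene_list))
    readLines(config$gene_list, warn = FALSE) else up
  gene_list <- gene_list[nzchar(gene_list)]
  survivors <- with_stage("iterative_km", iterative_km(
    expr, clin, gene_list, endpoint = config$endpoint, test = config$test,
    alpha = config$alpha))
  run_log(log_con, "iterative_km",
          sprintf("%d/%d genes significant at alpha=%g; poor fraction %.3g",
                  nrow(survivors), attr(survivors, "n_tested"),
                  config$alpha, attr(survivors, "poor_fraction")))
  write_screen(survivors, file.path(out_dir, "prognostic_survivors.tsv"),
               header_comment = header)
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    lib <- with_stage("read_gmt", read_gmt(config$gene_sets))
    enrichment <- if (nrow(survivors)) {
      with_stage("enrich",
                 enrich_gene_sets(survivors$gene, rownames(expr), lib))
    } else {
      data.frame(set = character(0), overlap = integer(0),
                 set_size = integer(0), target_size = integer(0),
                 universe_size = integer(0), p_value = numeric(0),
                 q_value = numeric(0), genes = character(0),
                 stringsAsFactors = FALSE)
    }
    write_table_with_header(as.data.frame(enrichment),
                            file.path(out_dir, "enrichment.tsv"), header)
    run_log(log_con, "enrich",
            sprintf("%d sets tested, best p=%.3g", nrow(enrichment),
                    if (nrow(enrichment)) enrichment$p_value[1] else NA))
  }
  invisible(list(de = de, upregulated = up, survivors = survivors,
                 enrichment = enrichment, output_dir = out_dir))
}
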