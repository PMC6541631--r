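#' Construct an expression matrix
#'
#' Container for a genes x samples expression matrix, tracking whether the
#' values have been per-gene Z-score normalized. Row names are gene
#' identifiers, column names are sample identifiers; both must be unique.
#'
#' @param values Numeric matrix (genes x samples) with unique rownames and
#'   colnames.
#' @param normalized Logical; `TRUE` if each gene row is already Z-scored
#'   (mean 0, sd 1 across samples).
#' @return An object of class `ExpressionMatrix`: the matrix with attributes
#'   `normalized` and (after [zscore_normalize()]) `constant_genes`.
#' @seealso [read_expression()], [zscore_normalize()]
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  structure(values, normalized = isTRUE(normalized),
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "Z-score normalized" else "raw"))
  invisible(x)
}

#' Is an expression matrix Z-score normalized?
#' @param x An `ExpressionMatrix`.
#' @return Logical flag.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

gene_ids <- function(x) rownames(x)
sample_ids <- function(x) colnames(x)

#' Read a genes-x-samples expression TSV
#'
#' Reads a tab-delimited expression table with genes as rows. The first
#' column holds the gene identifier; remaining columns are samples. The
#' `cbioportal` dialect additionally tolerates a second Entrez-id column
#' (dropped on read) and literal `"NA"` cells.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"plain"` or `"cbioportal"`.
#' @return An [expression_matrix()] with `normalized = FALSE`.
#' @export
read_expression <- function(path, dialect = c("plain", "cbioportal")) {
  dialect <- match.arg(dialect)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", colClasses = "character")
  if (ncol(df) < 2) stop("expression table needs a gene column and >=1 sample")
  if (dialect == "cbioportal" && ncol(df) >= 2 &&
      grepl("entrez", names(df)[2], ignore.case = TRUE))
    df <- df[, -2, drop = FALSE]
  genes <- df[[1]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(genes, names(vals)))
  for (j in seq_len(ncol(vals))) {
    cell <- vals[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "NA" & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (gene %s), column '%s'",
                   cell[bad[1]], bad[1], genes[bad[1]], names(vals)[j]))
    m[, j] <- num
  }
  expression_matrix(m, normalized = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] (plain dialect); missing values are
#' written as `NA`. Full-precision values so round trips are bit-exact.
#'
#' @param x An `ExpressionMatrix` (or any named numeric matrix).
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  write_matrix_tsv(x, path, id_col = "gene_id")
}

write_matrix_tsv <- function(x, path, id_col) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r)
    paste(ifelse(is.na(r), "NA", format(r, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Per-gene Z-score normalization
#'
#' Standardizes each gene row to mean 0, sd 1 across samples, using the
#' sample standard deviation (denominator n-1) over non-missing values.
#' Genes that are constant (or have fewer than two non-missing values) are
#' set wholly missing and recorded in the `constant_genes` attribute.
#'
#' @param m An `ExpressionMatrix` with `normalized = FALSE`.
#' @return A normalized `ExpressionMatrix` (`normalized = TRUE`).
#' @export
zscore_normalize <- function(m) {
  if (!inherits(m, "ExpressionMatrix")) m <- expression_matrix(m)
  if (is_normalized(m))
    stop("expression matrix is already Z-score normalized")
  v <- unclass(m)
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1, stats::sd, na.rm = TRUE)
  nn <- rowSums(!is.na(v))
  const <- rownames(v)[is.na(sd_) | sd_ == 0 | nn < 2]
  z <- (v - mu) / sd_
  if (length(const)) z[const, ] <- NA_real_
  out <- expression_matrix(z, normalized = TRUE)
  attr(out, "constant_genes") <- const
  out
}

#' Construct a clinical table
#'
#' Per-patient survival endpoints: overall survival (OS) always, disease-free
#' survival (DFS) optionally. Missing endpoints are `NA`, never silently zero.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param os_months,os_event OS time in months (>= 0) and event indicator
#'   (1 = death observed, 0 = right-censored).
#' @param dfs_months,dfs_event Optional DFS endpoint, same conventions.
#' @param subtype Optional categorical subtype label.
#' @return A `data.frame` of class `ClinicalTable`.
#' @export
clinical_table <- function(sample_id, os_months, os_event,
                           dfs_months = NULL, dfs_event = NULL,
                           subtype = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  check_endpoint <- function(time, event, what) {
    if (any(time < 0, na.rm = TRUE))
      stop("negative ", what, " time")
    if (!all(event %in% c(0, 1, NA)))
      stop(what, " event indicator must be 0/1")
  }
  check_endpoint(os_months, os_event, "OS")
  df <- data.frame(sample_id = sample_id, os_months = as.numeric(os_months),
                   os_event = as.integer(os_event),
                   stringsAsFactors = FALSE)
  if (!is.null(dfs_months)) {
    check_endpoint(dfs_months, dfs_event, "DFS")
    df$dfs_months <- as.numeric(dfs_months)
    df$dfs_event <- as.integer(dfs_event)
  }
  if (!is.null(subtype)) df$subtype <- as.character(subtype)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

# cBioPortal-style status strings -> 0/1; returns NA for unparsable values
parse_status <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0", "0:LIVING", "LIVING", "0:DiseaseFree", "DiseaseFree")] <- 0L
  out[x %in% c("1", "1:DECEASED", "DECEASED",
               "1:Recurred/Progressed", "Recurred/Progressed")] <- 1L
  out
}

#' Read a clinical survival TSV
#'
#' Expects columns `sample_id`, `os_months`, `os_status` and optionally
#' `dfs_months`, `dfs_status` (plus optional `subtype`). The `cbioportal`
#' status dialect accepts `"0:LIVING"`/`"1:DECEASED"` and
#' `"0:DiseaseFree"`/`"1:Recurred/Progressed"`; the `plain` dialect accepts
#' 0/1. Rows whose OS status cannot be parsed are dropped with a message
#' reporting the count.
#'
#' @param path Path to a TSV with header.
#' @param status_dialect `"plain"` or `"cbioportal"` (both parsers accept
#'   either encoding; the argument documents the expected source).
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path, status_dialect = c("plain", "cbioportal")) {
  match.arg(status_dialect)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "os_months", "os_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  os_time <- suppressWarnings(as.numeric(df$os_months))
  if (any(os_time < 0, na.rm = TRUE)) stop("negative OS time")
  os_event <- parse_status(df$os_status)
  bad <- is.na(os_event) & !is.na(df$os_status)
  if (any(bad))
    message(sum(bad), " row(s) with unparsable OS status dropped")
  keep <- !bad
  has_dfs <- all(c("dfs_months", "dfs_status") %in% names(df))
  if (has_dfs) {
    dfs_time <- suppressWarnings(as.numeric(df$dfs_months))
    if (any(dfs_time < 0, na.rm = TRUE)) stop("negative DFS time")
    dfs_event <- parse_status(df$dfs_status)
  }
  clinical_table(df$sample_id[keep], os_time[keep], os_event[keep],
                 dfs_months = if (has_dfs) dfs_time[keep],
                 dfs_event = if (has_dfs) dfs_event[keep],
                 subtype = if ("subtype" %in% names(df)) df$subtype[keep])
}

#' Write a clinical table as TSV
#' @param x A `ClinicalTable`.
#' @param path Output path.
#' @export
write_clinical <- function(x, path) {
  out <- data.frame(sample_id = x$sample_id,
                    os_months = x$os_months, os_status = x$os_event,
                    stringsAsFactors = FALSE)
  if (!is.null(x$dfs_months)) {
    out$dfs_months <- x$dfs_months
    out$dfs_status <- x$dfs_event
  }
  if (!is.null(x$subtype)) out$subtype <- x$subtype
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct / read a GISTIC-style copy-number call table
#'
#' Integer calls per gene and sample: -2 deep deletion, -1 heterozygous
#' loss, 0 diploid, 1 gain, 2 amplification.
#'
#' @param calls Integer matrix (genes x samples) with values in -2..2 or NA.
#' @return A matrix of class `CopyNumberTable`.
#' @export
copy_number_table <- function(calls) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(calls)) || anyDuplicated(colnames(calls)))
    stop("duplicate identifiers in copy-number table")
  ok <- is.na(calls) | calls %in% (-2):2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("copy-number call %s outside {-2..2} at gene %s, sample %s",
                 calls[bad[1], bad[2]], rownames(calls)[bad[1]],
                 colnames(calls)[bad[2]]))
  }
  storage.mode(calls) <- "integer"
  structure(calls, class = c("CopyNumberTable", "matrix", "array"))
}

#' @rdname copy_number_table
#' @param path Path to a TSV laid out like an expression table with integer
#'   cells.
#' @export
read_copy_number <- function(path) {
  m <- read_expression(path, dialect = "plain")
  copy_number_table(unclass(m))
}

#' Write a copy-number table as TSV
#' @param x A `CopyNumberTable`.
#' @param path Output path.
#' @export
write_copy_number <- function(x, path) {
  write_matrix_tsv(x, path, id_col = "gene_id")
}

#' Ligand-to-receptor pairing map
#'
#' Maps each ligand (cytokine) gene to its receptor gene(s). On disk the
#' format is one line per ligand: `ligand<TAB>receptor[,receptor...]`.
#'
#' @param pairs Named list: names are ligand gene ids, values non-empty
#'   character vectors of receptor gene ids.
#' @return A list of class `PairingMap`.
#' @export
pairing_map <- function(pairs) {
  if (is.null(names(pairs)) || any(names(pairs) == ""))
    stop("every pairing entry must be named by its ligand")
  if (anyDuplicated(names(pairs)))
    stop("duplicate ligand identifier(s): ",
         paste(unique(names(pairs)[duplicated(names(pairs))]), collapse = ", "))
  if (any(!lengths(pairs)))
    stop("empty receptor list for ligand(s): ",
         paste(names(pairs)[!lengths(pairs)], collapse = ", "))
  structure(lapply(pairs, as.character), class = "PairingMap")
}

#' @rdname pairing_map
#' @param path Path to a two-column TSV (`ligand`, `receptors` with
#'   comma-separated receptor ids); a header row is required.
#' @export
read_pairing <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("pairing table needs ligand and receptor columns")
  recs <- strsplit(as.character(df[[2]]), ",", fixed = TRUE)
  recs <- lapply(recs, trimws)
  names(recs) <- as.character(df[[1]])
  pairing_map(recs)
}

#' Write a pairing map as TSV
#' @param x A `PairingMap`.
#' @param path Output path.
#' @export
write_pairing <- function(x, path) {
  df <- data.frame(ligand = names(x),
                   receptors = vapply(x, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set library (GMT)
#'
#' @param sets Named list of non-empty character vectors of gene ids.
#' @param name Library name.
#' @return A list of class `GeneSetLibrary` with attribute `library_name`.
#' @export
gene_set_library <- function(sets, name = "library") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  if (any(!lengths(sets)))
    stop("empty gene set(s): ",
         paste(names(sets)[!lengths(sets)], collapse = ", "))
  structure(lapply(sets, as.character), library_name = name,
            class = "GeneSetLibrary")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one tab-separated line per set, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @param name Library name (default: file basename).
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_library(sets, name = name)
}

#' Write a gene-set library as GMT
#' @param x A `GeneSetLibrary`.
#' @param path Output path.
#' @export
write_gmt <- function(x, path) {
  writeLines(vapply(names(x), function(nm)
    paste(c(nm, "na", x[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Align expression, clinical and copy-number tables on shared samples
#'
#' Takes the intersection of sample identifiers and subsets every table to
#' it, preserving the expression matrix's sample order. The counts dropped
#' from each table are reported with a message (real cohort exports rarely
#' agree exactly on their patient sets).
#'
#' @param expr An `ExpressionMatrix`.
#' @param clinical A `ClinicalTable`.
#' @param cn Optional `CopyNumberTable`.
#' @return A list with elements `expr`, `clinical`, (optionally `cn`) and
#'   `n` = number of shared samples.
#' @export
align_cohort <- function(expr, clinical, cn = NULL) {
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (!is.null(cn)) ids <- intersect(ids, colnames(cn))
  if (!length(ids)) stop("no shared samples across tables")
  dropped <- c(expression = ncol(expr) - length(ids),
               clinical = nrow(clinical) - length(ids),
               copy_number = if (!is.null(cn)) ncol(cn) - length(ids))
  if (any(dropped > 0))
    message("align_cohort: using ", length(ids), " shared samples (dropped ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "),
            ")")
  ids <- colnames(expr)[colnames(expr) %in% ids]
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  out <- list(expr = expr[, ids, drop = FALSE], clinical = cl, n = length(ids))
  attr(out$expr, "normalized") <- attr(expr, "normalized")
  class(out$expr) <- class(expr)
  class(cl) <- class(clinical)
  out$clinical <- cl
  if (!is.null(cn)) out$cn <- cn[, ids, drop = FALSE]
  out
}

# Pull one endpoint from a clinical table as list(time, event), dropping
# samples with a missing time or status.
endpoint_columns <- function(clinical, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") {
    time <- clinical$os_months; event <- clinical$os_event
  } else {
    if (is.null(clinical$dfs_months))
      stop("clinical table has no DFS endpoint")
    time <- clinical$dfs_months; event <- clinical$dfs_event
  }
  ok <- !is.na(time) & !is.na(event)
  list(time = time[ok], event = event[ok], sample_id = clinical$sample_id[ok])
}
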