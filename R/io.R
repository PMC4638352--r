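#' Read a methylation beta-value matrix
#'
#' Reads a tab-separated matrix of beta values (fraction methylated signal,
#' in \[0,1\]). The on-disk convention follows array-platform exports: one CpG
#' probe per row, one sample per column, with probe identifiers in the first
#' column and sample identifiers in the header. Gzipped files are read
#' transparently. The returned matrix is oriented samples x CpGs.
#'
#' Missing cells (empty, `NA`, `NaN`, `null`) are kept as `NA`, never coerced
#' to zero; any non-missing value outside \[0,1\] is an error naming the
#' offending probe and sample.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @param orientation `"features_rows"` (default; probes in rows) or
#'   `"samples_rows"` for transposed files.
#' @return A numeric matrix, samples in rows (rownames = sample ids), CpG
#'   probes in columns (colnames = probe ids).
#' @export
read_methylation_matrix <- function(path, orientation = c("features_rows", "samples_rows")) {
  m <- read_id_matrix(path, orientation)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (value %g)",
      colnames(m)[bad[1, 2]], rownames(m)[bad[1, 1]], m[bad[1, , drop = FALSE]]
    ), call. = FALSE)
  }
  m
}

#' Read a gene expression matrix
#'
#' Same file dialect as [read_methylation_matrix()] (genes in rows, samples in
#' columns by default) without the \[0,1\] bound: expression is
#' platform-scale continuous.
#'
#' @inheritParams read_methylation_matrix
#' @return A numeric matrix, samples x genes.
#' @export
read_expression_matrix <- function(path, orientation = c("features_rows", "samples_rows")) {
  read_id_matrix(path, orientation)
}

# Shared TSV matrix reader; returns samples x features.
read_id_matrix <- function(path, orientation = c("features_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, check.names = FALSE,
                      na.strings = c("NA", "NaN", "null", ""), comment.char = "#"),
    error = function(e) stop(sprintf("malformed matrix file '%s': %s", path, conditionMessage(e)), call. = FALSE)
  )
  if (ncol(df) < 2) stop(sprintf("malformed header in '%s': need an id column plus data columns", path), call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row identifier '%s' in '%s'", ids[duplicated(ids)][1], path), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  if (anyDuplicated(colnames(vals))) {
    stop(sprintf("duplicate column identifier '%s' in '%s'",
                 colnames(vals)[duplicated(colnames(vals))][1], path), call. = FALSE)
  }
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))][1]
    stop(sprintf("non-numeric data column '%s' in '%s'", nonnum, path), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "features_rows") m <- t(m)
  m
}

#' Read a clinical outcome table
#'
#' Expects a tab-separated table with the columns `sample_id`, `os_time`
#' (overall-survival time in days), `os_event` (1 = death observed,
#' 0 = censored), `age_group` (`<=55` / `>=56`), `stage_group`
#' (`I&II` / `III&IV`), `size_group` (`1-2` / `3-4`) and receptor statuses
#' `er`, `pr`, `her2` (`+` / `-` / `unknown`). Missing categorical entries
#' are mapped to `"unknown"`; unrecognized levels and negative times are
#' errors.
#'
#' @param path Path to a TSV (optionally gzipped) file.
#' @return A `data.frame`, one row per sample.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "#",
                          colClasses = "character")
  needed <- c("sample_id", "os_time", "os_event", "age_group", "stage_group",
              "size_group", "er", "pr", "her2")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("clinical table '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    os_time = as.numeric(df$os_time),
    os_event = as.numeric(df$os_event),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in clinical table", call. = FALSE)
  }
  if (any(out$os_time < 0, na.rm = TRUE)) {
    bad <- out$sample_id[which(out$os_time < 0)][1]
    stop(sprintf("negative os_time for sample '%s'", bad), call. = FALSE)
  }
  if (!all(out$os_event %in% c(0, 1, NA))) {
    stop("os_event must be 0 or 1", call. = FALSE)
  }
  out$age_group <- check_levels(df$age_group, c("<=55", ">=56"), "age_group")
  out$stage_group <- check_levels(df$stage_group, c("I&II", "III&IV"), "stage_group")
  out$size_group <- check_levels(df$size_group, c("1-2", "3-4"), "size_group")
  for (rc in c("er", "pr", "her2")) {
    out[[rc]] <- check_levels(df[[rc]], c("+", "-"), rc, allow_unknown = TRUE)
  }
  rownames(out) <- out$sample_id
  out
}

check_levels <- function(x, levels, what, allow_unknown = TRUE) {
  x <- as.character(x)
  x[is.na(x)] <- "unknown"
  ok <- x %in% c(levels, if (allow_unknown) "unknown")
  if (!all(ok)) {
    stop(sprintf("unrecognized %s level '%s'", what, x[!ok][1]), call. = FALSE)
  }
  x
}

#' Read a promoter map (gene to CpG probe assignment)
#'
#' Accepts a two-column TSV `gene_id<TAB>cpg_id` (header optional) or a
#' BED-style probe annotation with at least four columns, where the name
#' field holds the gene and the probe id is formed as `chrom:start-end`.
#' Probe order within a gene follows file order; a probe listed twice for
#' the same gene is an error.
#'
#' @param path Path to the map file (optionally gzipped).
#' @return A named list: `gene_id -> character vector of cpg ids`.
#' @export
read_promoter_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                           comment.char = "#", colClasses = "character")
  if (ncol(raw) >= 4 &&
      !anyNA(suppressWarnings(as.numeric(raw[[2]]))) &&
      !anyNA(suppressWarnings(as.numeric(raw[[3]])))) {
    gene <- raw[[4]]
    cpg <- sprintf("%s:%s-%s", raw[[1]], raw[[2]], raw[[3]])
  } else {
    if (ncol(raw) < 2) stop(sprintf("promoter map '%s' needs two columns", path), call. = FALSE)
    gene <- raw[[1]]
    cpg <- raw[[2]]
    if (identical(tolower(gene[1]), "gene_id")) { # optional header row
      gene <- gene[-1]
      cpg <- cpg[-1]
    }
  }
  pmap <- split(cpg, factor(gene, levels = unique(gene)))
  dup <- vapply(pmap, anyDuplicated, integer(1))
  if (any(dup > 0)) {
    g <- names(pmap)[dup > 0][1]
    stop(sprintf("probe '%s' listed twice for gene '%s'", pmap[[g]][dup[[g]]], g), call. = FALSE)
  }
  pmap
}

#' Align cohorts and remove incomplete features
#'
#' Restricts the methylation matrix, expression matrix and clinical table to
#' their common samples, then removes incomplete data: samples missing the
#' survival outcome are dropped first, then any CpG probe or expression gene
#' with a missing or non-finite value in the retained samples. Removal
#' counts are reported via `message()`.
#'
#' The operation is idempotent and leaves complete inputs untouched.
#'
#' @param meth Samples x CpGs beta matrix.
#' @param expr Samples x genes expression matrix.
#' @param clin Clinical `data.frame` as from [read_clinical_table()].
#' @return A list with elements `meth`, `expr`, `clin`, sample-aligned in
#'   identical order.
#' @export
filter_missing <- function(meth, expr, clin) {
  shared <- Reduce(intersect, list(rownames(meth), rownames(expr), clin$sample_id))
  if (length(shared) == 0) {
    stop("no samples shared between methylation, expression and clinical inputs", call. = FALSE)
  }
  clin <- clin[match(shared, clin$sample_id), , drop = FALSE]
  has_outcome <- is.finite(clin$os_time) & clin$os_event %in% c(0, 1)
  if (any(!has_outcome)) {
    message(sprintf("filter_missing: dropped %d sample(s) missing survival outcome", sum(!has_outcome)))
  }
  keep <- shared[has_outcome]
  clin <- clin[has_outcome, , drop = FALSE]
  meth <- meth[keep, , drop = FALSE]
  expr <- expr[keep, , drop = FALSE]

  cpg_ok <- colSums(!is.finite(meth)) == 0
  gene_ok <- colSums(!is.finite(expr)) == 0
  message(sprintf(
    "filter_missing: %d samples retained; removed %d/%d CpG(s) and %d/%d gene(s) with missing values",
    length(keep), sum(!cpg_ok), ncol(meth), sum(!gene_ok), ncol(expr)
  ))
  list(
    meth = meth[, cpg_ok, drop = FALSE],
    expr = expr[, gene_ok, drop = FALSE],
    clin = clin
  )
}

# Writers for the same dialects (used by the simulator and the pipeline).

write_id_matrix <- function(m, path, id_col) {
  # m is samples x features; written features-in-rows per platform convention
  tm <- t(m)
  df <- data.frame(id = rownames(tm), tm, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_clinical_table <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_promoter_map <- function(pmap, path) {
  df <- data.frame(
    gene_id = rep(names(pmap), lengths(pmap)),
    cpg_id = unlist(pmap, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
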