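# I/O for expression matrices, case-control studies, gene lists and result
# tables. An expression matrix is an ordinary numeric matrix: genes in rows,
# samples in columns, dimnames carrying the identifiers. Values are normalized
# abundances (RPKM/FPKM/TPM-like); every downstream statistic is rank- or
# threshold-based within one dataset, so the specific unit is immaterial.

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants every pipeline stage relies on: unique gene and sample
#' identifiers, and finite non-negative values. Missing genes must be absent
#' rows, never sentinel values.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_format("expression matrix must be a numeric matrix")
  g <- rownames(values); s <- colnames(values)
  if (is.null(g) || is.null(s))
    abort_format("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(g))
    abort_duplicate(sprintf("duplicate gene identifier(s): %s",
                            paste(unique(g[duplicated(g)]), collapse = ", ")))
  if (anyDuplicated(s))
    abort_duplicate(sprintf("duplicate sample identifier(s): %s",
                            paste(unique(s[duplicated(s)]), collapse = ", ")))
  if (any(!is.finite(values)))
    abort_value("expression values must all be finite")
  if (any(values < 0))
    abort_value("expression values must all be >= 0")
  invisible(values)
}

# strsplit() drops trailing empty fields; pad with a newline sentinel so that
# blank trailing cells survive, then strip it from the last field.
split_tsv_lines <- function(lines) {
  parts <- strsplit(paste0(lines, "\n"), "\t", fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\n$", "", p[length(p)])
    p
  })
}

parse_value_cells <- function(cells, where) {
  vals <- suppressWarnings(as.numeric(cells))
  if (any(is.na(vals)))
    abort_value(sprintf("non-numeric expression value in %s: '%s'",
                        where, cells[which(is.na(vals))[1L]]))
  vals
}

#' Read a GCT 1.2 expression matrix
#'
#' Expects the `#1.2` version tag on line 1 and the declared row/column counts
#' on line 2; the Description column is discarded (the pipeline operates on
#' identifiers only).
#'
#' @param path path to a GCT 1.2 file.
#' @return A validated gene-by-sample numeric matrix.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2")
    abort_format("not a GCT 1.2 file: missing '#1.2' version tag on line 1")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (length(dims) < 2L || any(is.na(dims[1:2])))
    abort_format("GCT line 2 must declare row and column counts")
  n_genes <- dims[1L]; n_samples <- dims[2L]
  header <- split_tsv_lines(lines[3L])[[1L]]
  if (length(header) != n_samples + 2L)
    abort_format(sprintf("GCT header has %d sample columns, %d declared",
                         length(header) - 2L, n_samples))
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes)
    abort_format(sprintf("GCT declares %d rows but contains %d", n_genes, length(body)))
  rows <- split_tsv_lines(body)
  bad <- which(lengths(rows) != n_samples + 2L)
  if (length(bad))
    abort_format(sprintf("GCT data row %d has %d columns, expected %d",
                         bad[1L], lengths(rows)[bad[1L]], n_samples + 2L))
  genes <- vapply(rows, `[[`, character(1L), 1L)
  if (anyDuplicated(genes))
    abort_duplicate(sprintf("duplicate gene identifier(s) in GCT: %s",
                            paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  values <- t(vapply(rows, function(r)
    parse_value_cells(r[-(1:2)], sprintf("row '%s'", r[[1L]])), numeric(n_samples)))
  if (n_samples == 1L) values <- matrix(values, ncol = 1L)
  dimnames(values) <- list(genes, header[-(1:2)])
  validate_expression_matrix(values)
  values
}

#' Read a TSV expression matrix
#'
#' First row holds sample identifiers (with or without a leading label for the
#' gene column), first column gene identifiers. A row whose value cells are all
#' blank is treated as gene-not-measured and dropped with a warning; a lone
#' blank or non-numeric cell is an error.
#'
#' @param path path to a tab-separated matrix.
#' @return A validated gene-by-sample numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 1L) abort_format("empty matrix file")
  rows <- split_tsv_lines(lines)
  header <- rows[[1L]]
  body <- rows[-1L]
  if (!length(body)) abort_format("matrix file has a header but no data rows")
  width <- lengths(body)
  if (length(unique(width)) != 1L)
    abort_format("ragged rows: data rows differ in column count")
  n_cols <- width[1L] - 1L
  if (n_cols < 1L) abort_format("matrix file has no sample columns")
  samples <- if (length(header) == n_cols) header else if (length(header) == n_cols + 1L)
    header[-1L] else abort_format("header column count does not match data rows")
  genes <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(genes))
    abort_duplicate(sprintf("duplicate gene identifier(s): %s",
                            paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  keep <- rep(TRUE, length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_cols)
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    if (all(!nzchar(trimws(cells)))) {
      warning(sprintf("dropping gene '%s': no measurements (fully blank row)", genes[i]),
              call. = FALSE)
      keep[i] <- FALSE
    } else {
      vals[i, ] <- parse_value_cells(cells, sprintf("row '%s'", genes[i]))
    }
  }
  vals <- vals[keep, , drop = FALSE]
  dimnames(vals) <- list(genes[keep], samples)
  validate_expression_matrix(vals)
  vals
}

#' Read a case-control study (matrix plus sample labels)
#'
#' The labels file is a two-column TSV mapping each sample identifier to
#' `case` or `control`. Samples present in the matrix but absent from the
#' labels file are excluded with a warning.
#'
#' @param matrix_path path to a TSV expression matrix of the study.
#' @param labels_path path to the two-column label file.
#' @return An object of class `case_control_study`: a list with elements
#'   `matrix`, `case_ids` and `control_ids`.
#' @export
read_case_control <- function(matrix_path, labels_path) {
  values <- read_tsv_matrix(matrix_path)
  if (!file.exists(labels_path)) abort_io(sprintf("file not found: %s", labels_path))
  lab_lines <- readLines(labels_path)
  lab_lines <- lab_lines[nzchar(trimws(lab_lines))]
  parts <- split_tsv_lines(lab_lines)
  if (any(lengths(parts) < 2L)) abort_format("labels file must have two tab-separated columns")
  ids <- vapply(parts, `[[`, character(1L), 1L)
  labs <- tolower(vapply(parts, `[[`, character(1L), 2L))
  if (identical(ids[1L], "sample_id") || labs[1L] %in% c("label", "group")) {
    ids <- ids[-1L]; labs <- labs[-1L]
  }
  if (!all(labs %in% c("case", "control")))
    abort_label(sprintf("labels must be 'case' or 'control'; saw '%s'",
                        labs[which(!labs %in% c("case", "control"))[1L]]))
  for (id in unique(ids[duplicated(ids)])) {
    if (length(unique(labs[ids == id])) > 1L)
      abort_label(sprintf("sample '%s' labelled both case and control", id))
  }
  keep1 <- !duplicated(ids)
  ids <- ids[keep1]; labs <- labs[keep1]
  case_control_study(values, ids[labs == "case"], ids[labs == "control"])
}

#' Construct a case-control study from in-memory pieces
#'
#' @param values gene-by-sample numeric matrix of the study.
#' @param case_ids,control_ids disjoint, non-empty subsets of `colnames(values)`.
#' @return An object of class `case_control_study`.
#' @export
case_control_study <- function(values, case_ids, control_ids) {
  validate_expression_matrix(values)
  known <- colnames(values)
  case_ids <- case_ids[case_ids %in% known]
  control_ids <- control_ids[control_ids %in% known]
  unlabeled <- setdiff(known, c(case_ids, control_ids))
  if (length(unlabeled)) {
    warning(sprintf("excluding %d unlabelled sample(s): %s", length(unlabeled),
                    paste(utils::head(unlabeled, 5L), collapse = ", ")), call. = FALSE)
    values <- values[, !(known %in% unlabeled), drop = FALSE]
  }
  if (length(intersect(case_ids, control_ids)))
    abort_label("case and control sample sets overlap")
  if (!length(case_ids) || !length(control_ids))
    abort_composition("study needs at least one case and one control sample")
  structure(list(matrix = values, case_ids = case_ids, control_ids = control_ids),
            class = "case_control_study")
}

#' @export
print.case_control_study <- function(x, ...) {
  cat(sprintf("case_control_study: %d genes, %d cases, %d controls\n",
              nrow(x$matrix), length(x$case_ids), length(x$control_ids)))
  invisible(x)
}

#' Read a gene list (plain or BED4)
#'
#' A plain file has one gene identifier per line; a BED-like file has four or
#' more tab-separated columns (chrom, start, end, gene), with 0-based
#' half-open intervals.
#'
#' @param path path to the list file.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (coordinates `NA` for plain lists).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  parts <- split_tsv_lines(lines)
  is_bed <- all(lengths(parts) >= 4L) &&
    !anyNA(suppressWarnings(as.integer(vapply(parts, `[[`, character(1L), 2L))))
  if (is_bed) {
    out <- data.frame(
      gene_id = vapply(parts, `[[`, character(1L), 4L),
      chrom = vapply(parts, `[[`, character(1L), 1L),
      start = as.integer(vapply(parts, `[[`, character(1L), 2L)),
      end = as.integer(vapply(parts, `[[`, character(1L), 3L)))
    if (any(out$start >= out$end))
      abort_format("BED intervals must satisfy start < end (0-based half-open)")
  } else {
    out <- data.frame(gene_id = trimws(vapply(parts, `[[`, character(1L), 1L)),
                      chrom = NA_character_, start = NA_integer_, end = NA_integer_)
  }
  if (anyDuplicated(out$gene_id))
    abort_duplicate(sprintf("duplicate gene identifier(s) in list: %s",
                            paste(unique(out$gene_id[duplicated(out$gene_id)]),
                                  collapse = ", ")))
  out
}

# Accept either a character vector or a gene-list data frame everywhere a set
# of gene identifiers is expected.
as_gene_ids <- function(x) {
  ids <- if (is.data.frame(x)) {
    if (!"gene_id" %in% names(x)) abort_argument("gene list data frame needs a gene_id column")
    as.character(x$gene_id)
  } else as.character(x)
  if (anyDuplicated(ids)) abort_duplicate("duplicate gene identifiers in gene list")
  ids
}

#' Write a result table as TSV
#'
#' Writes one header plus one row per record in input order. Columns whose
#' names look like p-values (`p_raw`, `p_bonferroni`, `p_empirical`,
#' `p_ranksum`, ...) are rendered in scientific notation with 6 significant
#' digits after the decimal point.
#'
#' @param records data frame of records sharing one schema.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  if (!is.data.frame(records)) abort_argument("records must be a data frame")
  out <- records
  for (nm in names(out)) {
    if (grepl("^p_", nm) && is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), NA,
                          formatC(out[[nm]], format = "e", digits = 6))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write records to '%s'", path))
  invisible(path)
}

#' Read back a result table written by [write_records()]
#'
#' @param path path to a TSV written by [write_records()].
#' @return A data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write an expression matrix as GCT 1.2
#'
#' @param values gene-by-sample numeric matrix.
#' @param path output path.
#' @param descriptions optional Description column; defaults to the gene ids.
#' @return The path, invisibly.
#' @export
write_gct <- function(values, path, descriptions = rownames(values)) {
  validate_expression_matrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(sprintf("%d\t%d", nrow(values), ncol(values)), con)
  writeLines(paste(c("Name", "Description", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(v) paste(format(v, digits = 15, trim = TRUE),
                                              collapse = "\t"))
  writeLines(paste(rownames(values), descriptions, body, sep = "\t"), con)
  invisible(path)
}

#' Write an expression matrix as TSV
#'
#' @param values gene-by-sample numeric matrix.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tsv_matrix <- function(values, path) {
  validate_expression_matrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(v) paste(format(v, digits = 15, trim = TRUE),
                                              collapse = "\t"))
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}
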