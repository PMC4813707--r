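# Reading, validating and filtering per-fraction quantitation tables.
# The MaxQuant proteinGroups dialect lives here and nowhere else:
# tab-delimited with a header; one "Intensity <k>" and one "iBAQ <k>" column
# per gel fraction; QC marker columns ("Potential contaminant", "Reverse",
# "Only identified by site") using the "+" convention; semicolon-separated
# protein group IDs with the majority protein first.

#' Construct a per-fraction quantitation table
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param gene_name Character vector of gene symbols.
#' @param intensity,ibaq Numeric matrices (proteins x fractions) of
#'   nonnegative values.
#' @param flag_contaminant,flag_reverse,flag_only_by_site Logical QC flags.
#' @param fraction_labels Optional fraction column labels; defaults to
#'   `"1"..."F"`.
#' @return A validated `quant_table`.
#' @export
quant_table <- function(protein_id, gene_name, intensity, ibaq,
                        flag_contaminant = FALSE, flag_reverse = FALSE,
                        flag_only_by_site = FALSE, fraction_labels = NULL) {
  intensity <- as.matrix(intensity)
  ibaq <- as.matrix(ibaq)
  n <- length(protein_id)
  tab <- structure(
    list(
      proteins = data.frame(
        protein_id = as.character(protein_id),
        gene_name = as.character(gene_name),
        flag_contaminant = rep_len(as.logical(flag_contaminant), n),
        flag_reverse = rep_len(as.logical(flag_reverse), n),
        flag_only_by_site = rep_len(as.logical(flag_only_by_site), n),
        stringsAsFactors = FALSE
      ),
      intensity = intensity,
      ibaq = ibaq,
      n_fractions = ncol(intensity),
      fraction_labels = fraction_labels %||% as.character(seq_len(ncol(intensity)))
    ),
    class = "quant_table"
  )
  rownames(tab$intensity) <- tab$proteins$protein_id
  rownames(tab$ibaq) <- tab$proteins$protein_id
  colnames(tab$intensity) <- tab$fraction_labels
  colnames(tab$ibaq) <- tab$fraction_labels
  validate_quant_table(tab)
}

#' Validate a quant_table against its invariants
#' @param tab A `quant_table`.
#' @return The table, or a format error.
#' @export
validate_quant_table <- function(tab) {
  if (!inherits(tab, "quant_table")) abort_format("not a quant_table")
  n <- nrow(tab$proteins)
  if (nrow(tab$intensity) != n || nrow(tab$ibaq) != n) {
    abort_format("intensity/ibaq row count does not match protein records")
  }
  if (ncol(tab$intensity) != tab$n_fractions || ncol(tab$ibaq) != tab$n_fractions) {
    abort_format("fraction vector length mismatch")
  }
  if (anyDuplicated(tab$proteins$protein_id)) {
    abort_format("duplicate protein_id in table")
  }
  if (any(tab$intensity < 0) || any(tab$ibaq < 0)) {
    abort_format("negative quantitation value")
  }
  tab
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("<quant_table> %d proteins x %d fractions\n",
              nrow(x$proteins), x$n_fractions))
  flagged <- with(x$proteins, flag_contaminant | flag_reverse | flag_only_by_site)
  cat(sprintf("  QC-flagged records: %d\n", sum(flagged)))
  invisible(x)
}

#' Number of protein records in a quant_table
#' @param tab A `quant_table`.
#' @return Integer count.
#' @export
n_proteins <- function(tab) nrow(tab$proteins)

fraction_columns <- function(cols, pattern) {
  rx <- paste0("^", pattern, " (\\d+)$")
  hit <- grepl(rx, cols)
  idx <- which(hit)
  suffix <- as.integer(sub(rx, "\\1", cols[idx]))
  idx[order(suffix)]
}

parse_numeric_cells <- function(x, what) {
  x[is.na(x) | x == ""] <- "0"
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) abort_format(sprintf("non-numeric %s cell", what))
  if (any(v < 0)) abort_format(sprintf("negative %s value", what))
  v
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Fraction columns are matched as `"<pattern> <k>"` and ordered by their
#' numeric suffix `k` regardless of file order. Missing or blank cells are
#' read as 0 (never imputed). The canonical `protein_id` is the first entry
#' of the semicolon-separated protein-group identifier. QC flags are parsed
#' from the `"+"` marker columns when present.
#'
#' @param path Path to a tab-delimited file.
#' @param fraction_column_pattern Prefix of the intensity fraction columns
#'   (default `"Intensity"`).
#' @param ibaq_column_pattern Prefix of the iBAQ fraction columns (default
#'   `"iBAQ"`); must cover the same fraction suffixes.
#' @return A [quant_table()].
#' @export
read_quant_table <- function(path, fraction_column_pattern = "Intensity",
                             ibaq_column_pattern = "iBAQ") {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  cols <- names(df)
  int_idx <- fraction_columns(cols, fraction_column_pattern)
  if (length(int_idx) < 2L) {
    abort_format(sprintf("fewer than 2 columns match \"%s <k>\"",
                         fraction_column_pattern))
  }
  ibaq_idx <- fraction_columns(cols, ibaq_column_pattern)
  if (length(ibaq_idx) != length(int_idx)) {
    abort_format("iBAQ fraction columns do not mirror intensity columns")
  }
  nf <- length(int_idx)
  nr <- nrow(df)

  id_col <- if ("Protein IDs" %in% cols) "Protein IDs" else cols[1]
  raw_ids <- df[[id_col]]
  protein_id <- vapply(strsplit(raw_ids, ";", fixed = TRUE),
                       function(p) p[1], character(1))
  if (anyDuplicated(protein_id)) abort_format("duplicate protein_id in file")
  gene_name <- if ("Gene names" %in% cols) {
    vapply(strsplit(ifelse(is.na(df[["Gene names"]]) | df[["Gene names"]] == "",
                           protein_id, df[["Gene names"]]),
                    ";", fixed = TRUE), function(p) p[1], character(1))
  } else protein_id

  read_mat <- function(idx, what) {
    m <- matrix(0, nrow = nr, ncol = nf)
    for (j in seq_along(idx)) m[, j] <- parse_numeric_cells(df[[idx[j]]], what)
    m
  }
  intensity <- read_mat(int_idx, "intensity")
  ibaq <- read_mat(ibaq_idx, "iBAQ")

  flag <- function(col) {
    if (col %in% cols) !is.na(df[[col]]) & df[[col]] == "+" else rep(FALSE, nr)
  }
  suffixes <- sub(paste0("^", fraction_column_pattern, " "), "", cols[int_idx])
  quant_table(
    protein_id = protein_id, gene_name = gene_name,
    intensity = intensity, ibaq = ibaq,
    flag_contaminant = flag("Potential contaminant"),
    flag_reverse = flag("Reverse"),
    flag_only_by_site = flag("Only identified by site"),
    fraction_labels = suffixes
  )
}

#' Write a quant_table in the same dialect read_quant_table() consumes
#' @param tab A `quant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(tab, path) {
  validate_quant_table(tab)
  mark <- function(x) ifelse(x, "+", "")
  out <- data.frame(
    `Protein IDs` = tab$proteins$protein_id,
    `Gene names` = tab$proteins$gene_name,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (j in seq_len(tab$n_fractions)) {
    out[[paste("Intensity", tab$fraction_labels[j])]] <-
      format(tab$intensity[, j], digits = 15, trim = TRUE, scientific = FALSE)
  }
  for (j in seq_len(tab$n_fractions)) {
    out[[paste("iBAQ", tab$fraction_labels[j])]] <-
      format(tab$ibaq[, j], digits = 15, trim = TRUE, scientific = FALSE)
  }
  out[["Only identified by site"]] <- mark(tab$proteins$flag_only_by_site)
  out[["Reverse"]] <- mark(tab$proteins$flag_reverse)
  out[["Potential contaminant"]] <- mark(tab$proteins$flag_contaminant)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a control list of nonspecific binders
#'
#' One protein identifier per line; blank lines and `#` comments skipped.
#'
#' @param path Text file path.
#' @return Character vector of identifiers (a ControlList).
#' @export
read_control_list <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Filter a quantitation table
#'
#' Removes every record with any QC flag set (contaminant, reverse,
#' only-identified-by-site). Records whose `protein_id` is in `controls`
#' (the nonspecific-binder list from control immunoprecipitations) are
#' removed by default, or merely annotated in an `is_control` column when
#' `annotate_controls = TRUE`. Surviving records keep their order and their
#' quantitation vectors untouched; filtering is idempotent.
#'
#' @param tab A `quant_table`.
#' @param controls Character vector of control protein IDs (or `NULL`).
#' @param annotate_controls If `TRUE`, keep control-list records and add an
#'   `is_control` column instead of removing them.
#' @return The filtered `quant_table`.
#' @export
filter_quant_table <- function(tab, controls = NULL, annotate_controls = FALSE) {
  validate_quant_table(tab)
  flagged <- with(tab$proteins, flag_contaminant | flag_reverse | flag_only_by_site)
  in_controls <- tab$proteins$protein_id %in% (controls %||% character(0))
  drop <- flagged | (!annotate_controls & in_controls)
  keep <- which(!drop)
  out <- tab
  out$proteins <- tab$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  out$intensity <- tab$intensity[keep, , drop = FALSE]
  out$ibaq <- tab$ibaq[keep, , drop = FALSE]
  if (annotate_controls) out$proteins$is_control <- in_controls[keep]
  out
}

#' Read a molecular weight marker ladder
#'
#' Two-column tab-delimited file (fraction, mass in kDa). Masses must be
#' strictly monotone when rows are ordered by fraction; the returned ladder
#' is sorted by fraction.
#'
#' @param path TSV path with columns `fraction` and `mass_kda` (a header is
#'   detected; headerless two-column files are accepted).
#' @return data.frame with integer `fraction` and numeric `mass_kda`.
#' @export
read_marker_ladder <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort_format("marker ladder needs 2 columns")
  ladder <- data.frame(fraction = as.integer(df[[1]]), mass_kda = as.numeric(df[[2]]))
  validate_ladder(ladder)
}

#' Validate a marker ladder
#' @param ladder data.frame with columns `fraction`, `mass_kda`.
#' @return The ladder sorted by fraction, or a validation error.
#' @export
validate_ladder <- function(ladder) {
  if (nrow(ladder) < 2L) abort_format("marker ladder needs >= 2 rows")
  if (any(is.na(ladder$fraction)) || any(is.na(ladder$mass_kda))) {
    abort_format("marker ladder has missing values")
  }
  if (any(ladder$mass_kda <= 0)) abort_format("marker masses must be positive")
  ladder <- ladder[order(ladder$fraction), , drop = FALSE]
  rownames(ladder) <- NULL
  if (anyDuplicated(ladder$fraction)) abort_format("duplicate ladder fraction")
  d <- diff(ladder$mass_kda)
  if (!(all(d > 0) || all(d < 0))) {
    abort_format("marker masses must be strictly monotone in fraction order")
  }
  ladder
}
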