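# Readers and writers for the plain-text formats the tool exchanges:
# expression tables (genes x samples, tab-delimited), GEO SeriesMatrix-style
# files, probe-to-gene maps, reference correlation matrices and report
# tables. Parsing is strict: ragged rows, duplicate sample ids and
# non-numeric cells are errors that name the offending line.

.missing_tokens <- c("", "na", "nan", "null")

.parse_numeric_cells <- function(cells, line_numbers) {
  low <- tolower(trimws(cells))
  miss <- low %in% .missing_tokens
  out <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-numeric cell '%s' at line %d",
                 cells[which(bad)[1]], line_numbers[which(bad)[1]]))
  }
  out[miss] <- NA_real_
  out
}

.parse_expression_lines <- function(lines, line_numbers, path) {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(rows) < 2)
    stop(sprintf("'%s': need a header line and at least one data row", path))
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("'%s': row with %d columns (expected %d) at line %d",
                 path, widths[bad], widths[1], line_numbers[bad]))
  }
  strip <- function(x) gsub('^"|"$', "", trimws(x))
  header <- strip(rows[[1]])
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop(sprintf("'%s': duplicate sample identifiers in header", path))
  body <- rows[-1]
  ids <- strip(vapply(body, `[[`, "", 1))
  ncell <- widths[1] - 1L
  vals <- matrix(NA_real_, length(body), ncell)
  for (j in seq_along(body)) {
    vals[j, ] <- .parse_numeric_cells(body[[j]][-1],
                                      rep(line_numbers[j + 1], ncell))
  }
  dimnames(vals) <- list(ids, sample_ids)
  vals
}

#' Read a tab-delimited expression table
#'
#' First column holds probe/gene identifiers, the header row holds sample
#' identifiers; genes as rows, samples as columns. Empty cells and the
#' tokens `NA`, `NaN`, `null` (case-insensitive) parse as missing. Ragged
#' rows, duplicate sample ids and other non-numeric cells are errors naming
#' the line.
#'
#' @param path Path to the file.
#' @return Numeric matrix with probe/gene row names and sample column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  .parse_expression_lines(lines[keep], which(keep), path)
}

#' Write an expression table as tab-delimited text
#'
#' @param values Numeric matrix (or `expression_study`) to write.
#' @param path Output path.
#' @param id_header Name of the identifier column in the header.
#' @export
write_expression_tsv <- function(values, path, id_header = "id") {
  if (inherits(values, "expression_study")) values <- values$values
  df <- data.frame(id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO SeriesMatrix-style expression table
#'
#' Lines beginning with `!` are metadata and ignored; the tab-delimited
#' table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` is parsed like [read_expression_tsv()].
#' Surrounding double quotes on identifiers are stripped.
#'
#' @param path Path to the file.
#' @return Numeric matrix with probe row names and sample column names.
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop(sprintf("'%s': series matrix table markers not found", path))
  idx <- seq(begin + 1, end - 1)
  idx <- idx[nzchar(lines[idx])]
  .parse_expression_lines(lines[idx], idx, path)
}

#' Read a probe-to-gene mapping table
#'
#' Two tab-delimited columns (probe id, gene id); an optional header line
#' `probe<TAB>gene` is skipped.
#'
#' @param path Path to the file.
#' @return Data frame with columns `probe` and `gene`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("probe", "gene"))
  if (nrow(df) > 0 && identical(tolower(unlist(df[1, ])),
                                c(probe = "probe", gene = "gene")))
    df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0) stop(sprintf("'%s': empty probe map", path))
  rownames(df) <- NULL
  df
}

#' Write a reference correlation matrix as tab-delimited text
#'
#' Square matrix of median Fisher-z values with a gene header row and
#' column; invalid entries written as `NA`. A leading comment line records
#' the number of contributing studies.
#'
#' @param reference A `reference_correlation`.
#' @param path Output path.
#' @export
write_reference_tsv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_correlation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#coexsnr_reference\tn_studies=%d", reference$n_studies),
             con)
  m <- reference$median_z
  m[!reference$valid] <- NA_real_
  df <- data.frame(gene = reference$gene_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference correlation matrix written by [write_reference_tsv()]
#'
#' @param path Path to the file.
#' @return A `reference_correlation` (validity from non-`NA` entries;
#'   `sigma_med` recomputed).
#' @export
read_reference_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path)
  n_studies <- NA_integer_
  meta <- grep("^#coexsnr_reference", lines, value = TRUE)
  if (length(meta) == 1) {
    m <- regmatches(meta, regexpr("n_studies=[0-9]+", meta))
    if (length(m)) n_studies <- as.integer(sub("n_studies=", "", m))
  }
  vals <- .parse_expression_lines(lines[!startsWith(lines, "#")],
                                  which(!startsWith(lines, "#")), path)
  if (nrow(vals) != ncol(vals) ||
      !identical(rownames(vals), colnames(vals)))
    stop(sprintf("'%s': reference matrix must be square with matching ids",
                 path))
  valid <- !is.na(vals)
  diag(valid) <- FALSE
  structure(
    list(gene_ids = rownames(vals),
         median_z = vals,
         valid = valid,
         n_studies = n_studies,
         sigma_med = .offdiag_sd(vals, valid)),
    class = "reference_correlation"
  )
}

#' Write a deterministic report table
#'
#' Tab-delimited with a header; floating-point values at 6 significant
#' digits; rows sorted by the given score column (ascending), ties broken by
#' the identifier column, so identical results always give byte-identical
#' files.
#'
#' @param results Non-empty data frame.
#' @param path Output path.
#' @param sort_by Name of the score column to sort by, or `NULL` to sort by
#'   the identifier column only.
#' @param id_col Name or index of the identifier column (default first).
#' @export
write_report <- function(results, path, sort_by = NULL, id_col = 1) {
  results <- as.data.frame(results, stringsAsFactors = FALSE)
  if (nrow(results) == 0) stop("empty results: nothing to report")
  ids <- as.character(results[[id_col]])
  ord <- if (!is.null(sort_by)) order(results[[sort_by]], ids) else order(ids)
  results <- results[ord, , drop = FALSE]
  for (j in seq_along(results)) {
    if (is.double(results[[j]]))
      results[[j]] <- formatC(results[[j]], digits = 6, format = "g")
  }
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
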