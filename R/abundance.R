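#' Protein abundance matrix
#'
#' The universal input of the package: a proteins-by-samples grid of
#' non-negative intensities on the as-published scale, with explicit missing
#' values (`NA`). Rows are proteins, columns are samples; both carry unique
#' identifiers.
#'
#' @param values Numeric matrix with unique, non-empty rownames (protein ids)
#'   and colnames (sample ids). `NA` marks a missing quantification; every
#'   non-missing cell must be finite.
#' @param source_label Free-text provenance string.
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values` and `source_label`.
#' @examples
#' m <- matrix(c(1, 2, NA, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' am <- abundance_matrix(m, "toy")
#' n_missing(am)
#' @export
abundance_matrix <- function(values, source_label = "") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  pid <- rownames(values)
  sid <- colnames(values)
  check_ids(pid, "protein")
  check_ids(sid, "sample")
  bad <- which(!is.na(values) & !is.finite(values))
  if (length(bad) > 0L) {
    stop("non-finite abundance value at position ", bad[1L], call. = FALSE)
  }
  structure(list(values = values, source_label = as.character(source_label)),
            class = "abundance_matrix")
}

check_ids <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids))) {
    stop(what, " ids must be present and non-empty", call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate ", what, " id: ", dup[1L], call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("abundance_matrix: %d proteins x %d samples (%d missing cells)\n",
              nrow(v), ncol(v), sum(is.na(v))))
  if (nzchar(x$source_label)) cat("source:", x$source_label, "\n")
  invisible(x)
}

#' @rdname abundance_matrix
#' @param m An `abundance_matrix`.
#' @export
protein_ids <- function(m) rownames(m$values)

#' @rdname abundance_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' @rdname abundance_matrix
#' @export
n_missing <- function(m) sum(is.na(m$values))

#' Read a wide protein-abundance table
#'
#' Parses a delimited text file with one header row of sample ids and a first
#' column of protein ids (or the transpose). Cells matching `missing_tokens`
#' become missing values. Validation failures (malformed header, duplicate
#' ids, ragged rows, non-numeric cells) are reported with the offending
#' row/column.
#'
#' @param path Path to a TSV (default) or CSV file; the separator is guessed
#'   from the extension unless `sep` is given.
#' @param missing_tokens Character vector of cell values to treat as missing.
#'   The default covers the conventions of published supplements.
#' @param rows_are_proteins If `FALSE` the file is transposed on read
#'   (columns are proteins).
#' @param sep Field separator; `NULL` to guess from the extension.
#' @param source_label Provenance string stored on the result; defaults to
#'   the file name.
#' @return An [abundance_matrix].
#' @export
read_abundance_matrix <- function(path,
                                  missing_tokens = c("", "NA", "NaN", "null"),
                                  rows_are_proteins = TRUE,
                                  sep = NULL,
                                  source_label = basename(path)) {
  sep <- sep %||% guess_sep(path)
  rows <- read_delim_lines(path, sep)
  if (length(rows) < 2L) {
    stop("malformed header: file must have a header row and at least one data row",
         call. = FALSE)
  }
  header <- rows[[1L]]
  if (length(header) < 2L) {
    stop("malformed header: expected an id column plus at least one value column",
         call. = FALSE)
  }
  col_ids <- header[-1L]
  nfield <- length(header)
  widths <- lengths(rows)
  ragged <- which(widths[-1L] != nfield)
  if (length(ragged) > 0L) {
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 ragged[1L] + 1L, widths[ragged[1L] + 1L], nfield),
         call. = FALSE)
  }
  body <- rows[-1L]
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), byrow = TRUE)
  miss <- matrix(cells %in% missing_tokens, nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !miss, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at data row %d, column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 col_ids[bad[1L, 2L]]),
         call. = FALSE)
  }
  vals[miss] <- NA_real_
  dimnames(vals) <- list(row_ids, col_ids)
  if (!rows_are_proteins) {
    vals <- t(vals)
  }
  abundance_matrix(vals, source_label = source_label)
}

#' Write an abundance matrix as TSV
#'
#' Emits a wide table with a single header row of sample ids; missing cells
#' are written as `NA`. Values use 6 significant digits by default;
#' `full_precision = TRUE` writes `%.17g`, which round-trips doubles exactly.
#'
#' @param m An [abundance_matrix].
#' @param path Output path.
#' @param full_precision Write full double precision.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path, full_precision = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  chr <- matrix(format_num(v, full_precision = full_precision),
                nrow = nrow(v))
  df <- data.frame(protein_id = rownames(v), chr,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("protein_id", colnames(v))
  write_tsv_file(df, path)
}
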