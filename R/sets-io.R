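#' Unordered protein pair set
#'
#' A set of unordered protein pairs, e.g. curated synthetic-lethal gene
#' pairs. Each unordered pair is stored once, with the lexicographically
#' smaller id first; self-pairs are not allowed.
#'
#' @param a,b Character vectors of partner identifiers (recycled pairwise).
#' @param label Free-text label (e.g. a reliability class).
#' @param evidence Optional character vector of per-pair evidence labels,
#'   retained for the first occurrence of each unordered pair.
#' @return An object of class `pair_set`: a list with a two-column character
#'   `pairs` data frame (`a`, `b`, optionally `evidence`) and `label`.
#' @export
pair_set <- function(a = character(), b = character(), label = "",
                     evidence = NULL) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped", call. = FALSE)
    a <- a[!self]
    b <- b[!self]
    if (!is.null(evidence)) evidence <- evidence[!self]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  pairs <- data.frame(a = lo[keep], b = hi[keep], stringsAsFactors = FALSE)
  if (!is.null(evidence)) pairs$evidence <- as.character(evidence)[keep]
  structure(list(pairs = pairs, label = as.character(label)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d unordered pairs", nrow(x$pairs)))
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of pairs in a pair set
#' @param ps A [pair_set].
#' @export
n_pairs <- function(ps) nrow(ps$pairs)

#' Read a pair list (e.g. synthetic-lethal interactions)
#'
#' Expects two columns (`gene_a`, `gene_b`) plus an optional third evidence
#' column. Pairs are de-duplicated as unordered pairs; self-pair rows are
#' dropped with a warning. When `reliability_filter` is supplied, rows whose
#' evidence label is not in the filter are dropped — this is how
#' highest-reliability interaction classes (e.g. low-throughput or CRISPR
#' evidence) are selected from a full database export.
#'
#' @param path Delimited text file; separator guessed from the extension.
#' @param reliability_filter Optional character vector of evidence labels to
#'   keep.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param label Label stored on the result.
#' @param sep Field separator; `NULL` to guess.
#' @return A [pair_set].
#' @export
read_pair_set <- function(path, reliability_filter = NULL, header = TRUE,
                          label = basename(path), sep = NULL) {
  sep <- sep %||% guess_sep(path)
  rows <- read_delim_lines(path, sep)
  if (header && length(rows) > 0L) rows <- rows[-1L]
  if (length(rows) == 0L) {
    return(pair_set(label = label))
  }
  widths <- lengths(rows)
  if (any(widths < 2L)) {
    stop(sprintf("row %d has fewer than 2 columns", which(widths < 2L)[1L]),
         call. = FALSE)
  }
  a <- vapply(rows, `[[`, character(1L), 1L)
  b <- vapply(rows, `[[`, character(1L), 2L)
  evidence <- NULL
  if (all(widths >= 3L)) {
    evidence <- vapply(rows, `[[`, character(1L), 3L)
  }
  if (!is.null(reliability_filter)) {
    if (is.null(evidence)) {
      stop("reliability_filter given but the file has no evidence column",
           call. = FALSE)
    }
    keep <- evidence %in% reliability_filter
    a <- a[keep]
    b <- b[keep]
    evidence <- evidence[keep]
  }
  pair_set(a, b, label = label, evidence = evidence)
}

#' Write a pair set as TSV
#' @param ps A [pair_set].
#' @param path Output path.
#' @export
write_pair_set <- function(ps, path) {
  stopifnot(inherits(ps, "pair_set"))
  df <- ps$pairs
  names(df)[1:2] <- c("gene_a", "gene_b")
  write_tsv_file(df, path)
}

#' Protein-to-term annotation map
#'
#' A flat many-to-many mapping from annotation terms (e.g. GO ids) to member
#' proteins, stored term-first. Member sets are de-duplicated; empty terms
#' are not stored.
#'
#' @param term_to_members Named list of character vectors (term id ->
#'   member protein ids).
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(term_to_members = list()) {
  stopifnot(is.list(term_to_members))
  if (length(term_to_members) > 0L) {
    check_ids(names(term_to_members), "term")
    term_to_members <- lapply(term_to_members, function(x) unique(as.character(x)))
    term_to_members <- term_to_members[lengths(term_to_members) > 0L]
  }
  structure(list(term_to_members = term_to_members), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  sz <- lengths(x$term_to_members)
  cat(sprintf("annotation_map: %d terms (member counts %s)\n",
              length(sz),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  invisible(x)
}

#' Read a flat protein-to-term annotation file
#'
#' Two-column delimited text (`protein_id`, `term_id`), many-to-many, e.g. a
#' flat export of a Uniprot GO mapping. The mapping is inverted into
#' term -> member sets with de-duplication. Blank ids are rejected with the
#' offending row number.
#'
#' @param path Input file; separator guessed from the extension.
#' @param header Does the file carry a header row? Default `TRUE`.
#' @param sep Field separator; `NULL` to guess.
#' @return An [annotation_map].
#' @export
read_annotation_map <- function(path, header = TRUE, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  rows <- read_delim_lines(path, sep)
  if (header && length(rows) > 0L) rows <- rows[-1L]
  if (length(rows) == 0L) {
    return(annotation_map())
  }
  widths <- lengths(rows)
  if (any(widths < 2L)) {
    stop(sprintf("row %d has fewer than 2 columns", which(widths < 2L)[1L]),
         call. = FALSE)
  }
  protein <- vapply(rows, `[[`, character(1L), 1L)
  term <- vapply(rows, `[[`, character(1L), 2L)
  blank <- which(!nzchar(protein) | !nzchar(term))
  if (length(blank) > 0L) {
    stop(sprintf("blank id at row %d", blank[1L]), call. = FALSE)
  }
  annotation_map(split(protein, term))
}

#' Write an annotation map as flat protein/term TSV
#' @param ann An [annotation_map].
#' @param path Output path.
#' @export
write_annotation_map <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_map"))
  tm <- ann$term_to_members
  df <- data.frame(
    protein_id = unlist(tm, use.names = FALSE),
    term_id = rep(names(tm), lengths(tm)),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
}

#' Two-condition replicate intensity table
#'
#' Replicate protein intensities for two named conditions, as produced by a
#' replicated proteomics experiment (e.g. chromosome proteomes from depleted
#' versus wild-type cells).
#'
#' @param protein_ids Character vector of unique protein ids.
#' @param a,b Numeric matrices of replicate intensities (proteins x
#'   replicates) for conditions A and B; `NA` pads missing replicates.
#' @param conditions Length-2 character vector naming conditions A and B.
#' @return An object of class `condition_table`.
#' @export
condition_table <- function(protein_ids, a, b, conditions = c("A", "B")) {
  check_ids(protein_ids, "protein")
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(nrow(a) == length(protein_ids), nrow(b) == length(protein_ids),
            length(conditions) == 2L)
  if (any(rowSums(!is.na(a)) < 1L) || any(rowSums(!is.na(b)) < 1L)) {
    stop("every protein needs at least one recorded replicate per condition",
         call. = FALSE)
  }
  rownames(a) <- rownames(b) <- protein_ids
  structure(list(protein_ids = protein_ids, a = a, b = b,
                 conditions = as.character(conditions)),
            class = "condition_table")
}

#' @export
print.condition_table <- function(x, ...) {
  cat(sprintf("condition_table: %d proteins; %s (%d reps) vs %s (%d reps)\n",
              length(x$protein_ids), x$conditions[1L], ncol(x$a),
              x$conditions[2L], ncol(x$b)))
  invisible(x)
}

#' Read a two-condition replicate table
#'
#' Expects columns `protein_id`, `<condA>_r1`, `<condA>_r2`, ...,
#' `<condB>_r1`, ... Replicate columns are matched by the condition-name
#' prefix before an underscore.
#'
#' @param path Input file.
#' @param conditions Length-2 character vector of condition names (A then B).
#' @param missing_tokens Cell values treated as missing.
#' @param sep Field separator; `NULL` to guess.
#' @return A [condition_table].
#' @export
read_condition_table <- function(path, conditions,
                                 missing_tokens = c("", "NA", "NaN", "null"),
                                 sep = NULL) {
  stopifnot(length(conditions) == 2L)
  am <- read_abundance_matrix(path, missing_tokens = missing_tokens, sep = sep)
  cols <- sample_ids(am)
  ca <- grepl(paste0("^", conditions[1L], "_"), cols)
  cb <- grepl(paste0("^", conditions[2L], "_"), cols)
  if (!any(ca) || !any(cb)) {
    stop("no replicate columns found for condition '",
         conditions[which(!c(any(ca), any(cb)))[1L]], "'", call. = FALSE)
  }
  condition_table(protein_ids(am),
                  am$values[, ca, drop = FALSE],
                  am$values[, cb, drop = FALSE],
                  conditions = conditions)
}

#' Write a condition table as TSV
#' @param ct A [condition_table].
#' @param path Output path.
#' @param full_precision Write full double precision.
#' @export
write_condition_table <- function(ct, path, full_precision = FALSE) {
  stopifnot(inherits(ct, "condition_table"))
  v <- cbind(ct$a, ct$b)
  colnames(v) <- c(paste0(ct$conditions[1L], "_r", seq_len(ncol(ct$a))),
                   paste0(ct$conditions[2L], "_r", seq_len(ncol(ct$b))))
  rownames(v) <- ct$protein_ids
  write_abundance_matrix(abundance_matrix(v, "condition_table"), path,
                         full_precision = full_precision)
}
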