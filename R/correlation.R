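#' All-vs-all Spearman correlation with explicit undefined-value policy
#'
#' @description
#' The correlation engine implements the core of the guilt-by-association
#' workflow: missing abundances are imputed as zeros, every protein's sample
#' vector is rank-transformed once (average ranks for ties — imputation
#' creates massive ties at zero, so the tie convention matters), and the
#' full protein-by-protein Spearman matrix is obtained as a standardized
#' rank cross-product. A protein whose vector is constant after imputation
#' has no defined rank correlation; such entries are set to 0 and tracked in
#' `undefined_mask` so downstream statistics can distinguish "no
#' association" from "not estimable".
#'
#' @param rho Symmetric numeric matrix in `[-1, 1]` with unit diagonal and
#'   identical row/column protein ids.
#' @param undefined_mask Symmetric logical matrix marking entries whose
#'   correlation was undefined (set to 0); diagonal is always `FALSE`.
#' @return `correlation_matrix_obj()` returns an object of class
#'   `correlation_matrix`.
#' @seealso [correlation_matrix()] to compute one from an
#'   [abundance_matrix].
#' @export
correlation_matrix_obj <- function(rho, undefined_mask = NULL) {
  stopifnot(is.matrix(rho), is.numeric(rho), nrow(rho) == ncol(rho))
  check_ids(rownames(rho), "protein")
  if (!identical(rownames(rho), colnames(rho))) {
    stop("row and column ids must match", call. = FALSE)
  }
  if (is.null(undefined_mask)) {
    undefined_mask <- matrix(FALSE, nrow(rho), ncol(rho),
                             dimnames = dimnames(rho))
  }
  stopifnot(is.logical(undefined_mask),
            identical(dim(undefined_mask), dim(rho)))
  if (max(abs(rho - t(rho))) > 1e-12) {
    stop("rho must be symmetric within 1e-12", call. = FALSE)
  }
  if (any(abs(diag(rho) - 1) > 0)) {
    stop("diagonal must be exactly 1", call. = FALSE)
  }
  if (any(rho > 1 + 1e-12) || any(rho < -1 - 1e-12)) {
    stop("entries must lie in [-1, 1]", call. = FALSE)
  }
  rho <- clamp_unit(rho)
  if (any(rho[undefined_mask] != 0)) {
    stop("undefined entries must have rho exactly 0", call. = FALSE)
  }
  structure(list(rho = rho, undefined_mask = undefined_mask),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d proteins (%d undefined off-diagonal entries)\n",
              nrow(x$rho), sum(x$undefined_mask)))
  invisible(x)
}

#' @rdname correlation_matrix_obj
#' @param c A `correlation_matrix`.
#' @export
corr_ids <- function(c) rownames(c$rho)

#' Impute zeros in place of missing abundances
#'
#' Replaces every missing cell with exactly 0, leaving all other cells
#' untouched. Zero imputation treats "not quantified" as "not detected",
#' which is what makes rank correlation across sparsely detected proteins
#' computable at all; proteins missing in most samples then become
#' near-constant vectors, which the correlation engine flags as undefined.
#'
#' @param m An [abundance_matrix].
#' @return An [abundance_matrix] with no missing cells.
#' @export
impute_zeros <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  v[is.na(v)] <- 0
  abundance_matrix(v, source_label = m$source_label)
}

#' Spearman correlation of two vectors with undefined flag
#'
#' Pearson correlation of average-ranked (mid-rank) vectors; with no ties
#' this equals the classical closed form `1 - 6 * sum(d^2) / (n * (n^2 - 1))`.
#' If either vector is constant the correlation is undefined: the value is
#' reported as 0 with `undefined = TRUE`.
#'
#' @param x,y Numeric vectors of equal length `>= 2`, no missing values
#'   (apply [impute_zeros()] first).
#' @return A list with elements `rho` (numeric) and `undefined` (logical).
#' @examples
#' spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho  # 0.6
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y), call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("need at least 2 observations", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values present; impute first", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = 0, undefined = TRUE))
  }
  list(rho = clamp_unit(stats::cor(rx, ry)), undefined = FALSE)
}

#' All-vs-all Spearman correlation matrix
#'
#' Computes the full symmetric Spearman matrix over proteins (rows) of an
#' abundance matrix. Missing values are zero-imputed first. The rank
#' transform is performed once per protein; the matrix of pairwise
#' correlations is then a cross-product of row-standardized ranks, which is
#' what makes atlas-scale inputs (tens of thousands of proteins, ~1000
#' samples) tractable. Entries involving a constant (post-imputation) row
#' are set to 0 and flagged in `undefined_mask`; the diagonal is defined as
#' exactly 1 regardless, so a query protein always heads its own ranked
#' association list.
#'
#' @param m An [abundance_matrix] with at least 2 samples.
#' @return A `correlation_matrix` (see [correlation_matrix_obj()]).
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- impute_zeros(m)$values
  n <- ncol(v)
  if (n < 2L) {
    stop("need at least 2 samples to correlate", call. = FALSE)
  }
  p <- nrow(v)
  ids <- rownames(v)
  rk <- matrix(0, p, n)
  for (i in seq_len(p)) {
    rk[i, ] <- rank(v[i, ])
  }
  rm(v)
  # rebind rather than introduce new names: at atlas scale (15k x 15k the
  # result alone is ~1.8 GB) every live intermediate counts
  rk <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(rk^2))
  const <- ss == 0
  rk <- rk / ifelse(const, 1, ss)
  # tcrossprod computes one triangle (dsyrk) and mirrors, so the result is
  # exactly symmetric; only clamping against fp overshoot is needed.
  rho <- tcrossprod(rk)
  rm(rk)
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  if (any(const)) {
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  diag(rho) <- 1
  mask <- matrix(FALSE, p, p)
  if (any(const)) {
    mask[const, ] <- TRUE
    mask[, const] <- TRUE
    diag(mask) <- FALSE
  }
  dimnames(rho) <- list(ids, ids)
  dimnames(mask) <- dimnames(rho)
  # invariants hold by construction; skip the O(p^2) re-validation pass so
  # atlas-scale matrices stay within memory
  structure(list(rho = rho, undefined_mask = mask),
            class = "correlation_matrix")
}

#' Write / read a correlation matrix as square TSV
#'
#' The matrix is written with a header row and first column of protein ids.
#' When any entry is undefined, a companion file `<path>.mask.tsv` records
#' the mask as 0/1.
#'
#' @param c A `correlation_matrix`.
#' @param path Output path.
#' @param full_precision Write full double precision (default `TRUE`: the
#'   matrix is an intermediate that downstream stages re-read).
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(c, path, full_precision = TRUE) {
  stopifnot(inherits(c, "correlation_matrix"))
  chr <- matrix(format_num(c$rho, full_precision = full_precision),
                nrow = nrow(c$rho))
  df <- data.frame(protein_id = rownames(c$rho), chr,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("protein_id", colnames(c$rho))
  write_tsv_file(df, path)
  if (any(c$undefined_mask)) {
    mk <- matrix(as.integer(c$undefined_mask), nrow = nrow(c$rho))
    dfm <- data.frame(protein_id = rownames(c$rho), mk,
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(dfm) <- c("protein_id", colnames(c$rho))
    write_tsv_file(dfm, paste0(path, ".mask.tsv"))
  }
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @export
read_correlation_matrix <- function(path) {
  am <- read_abundance_matrix(path, missing_tokens = character(),
                              source_label = basename(path))
  rho <- am$values
  mask_path <- paste0(path, ".mask.tsv")
  mask <- NULL
  if (file.exists(mask_path)) {
    mk <- read_abundance_matrix(mask_path, missing_tokens = character())
    mask <- mk$values == 1
    dimnames(mask) <- dimnames(rho)
  }
  correlation_matrix_obj(rho, mask)
}
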