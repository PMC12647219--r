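# Shared fixtures, built in code at test time.

# Small named random abundance matrix (no missing unless asked).
random_abundance <- function(p, n, seed, missing_frac = 0) {
  gbamine:::with_seed(seed, {
    v <- matrix(abs(rnorm(p * n, 10, 3)), p, n,
                dimnames = list(sprintf("P%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(n))))
    if (missing_frac > 0) {
      v[runif(p * n) < missing_frac] <- NA_real_
    }
    abundance_matrix(v, source_label = "fixture")
  })
}

# Correlation matrix built directly from a symmetric rho grid.
toy_correlation <- function(rho, ids = NULL) {
  ids <- ids %||% sprintf("P%d", seq_len(nrow(rho)))
  dimnames(rho) <- list(ids, ids)
  correlation_matrix_obj(rho)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write lines to a temp file and return its path.
tmp_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
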