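# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators never leak into (or depend on) global state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Clamp values into [-1, 1] without touching NAs.
clamp_unit <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# Format numeric columns for TSV output: 6 significant digits by default,
# %.17g when full precision is requested (round-trips doubles exactly).
format_num <- function(x, full_precision = FALSE, digits = 6L) {
  out <- if (full_precision) {
    sprintf("%.17g", x)
  } else {
    formatC(x, digits = digits, format = "g")
  }
  out[is.na(x)] <- "NA"
  out
}

# Write a data.frame as TSV with a single header row; numeric columns are
# pre-formatted by the caller so output bytes are deterministic.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

# Guess the field separator from a file extension: .csv -> comma, else tab.
guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Split a delimited file into a list of character vectors, one per line.
# Enforces a rectangular shape and reports the first offending line.
read_delim_lines <- function(path, sep) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(list())
  }
  strsplit(lines, sep, fixed = TRUE)
}
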