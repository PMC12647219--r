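#' Two-condition replicate differential abundance table
#'
#' Per-protein log2 fold change and significance for a replicated
#' two-condition design (e.g. chromosome proteomes from protein-depleted
#' versus wild-type cells, four replicates each). Intensities are
#' log2-transformed unless already on the log2 scale; the per-protein test
#' is a two-sided two-sample t comparison of replicate log2 values, with
#' Benjamini-Hochberg adjustment across all tested proteins. No variance
#' moderation or between-replicate normalization is applied (inputs are
#' assumed pre-normalized).
#'
#' The default test pools variances (`test = "student"`): at typical
#' replicate counts (n = 4 per condition) the pooled test holds its nominal
#' level exactly when replicate variances are comparable, whereas Welch's
#' random degrees of freedom make it noticeably conservative and less
#' sensitive at such small n. `test = "welch"` selects the unequal-variance
#' comparison for designs where condition variances genuinely differ.
#'
#' @param t A [condition_table]. Condition A is the reference: `log2fc` is
#'   condition B over condition A.
#' @param log_input Are intensities already log2-scale? If `FALSE` (default)
#'   raw intensities must be strictly positive and are log2-transformed.
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @return An object of class `differential_table`: a data frame with
#'   columns `protein`, `log2fc`, `p_value`, `q_value`, `n_a`, `n_b`.
#'   Proteins with fewer than 2 finite replicates in either condition are
#'   kept with `NA` statistics (and a warning), not silently dropped.
#'   Proteins whose replicates are all identical in both conditions get
#'   `p_value = 1` with a warning.
#' @export
differential_table <- function(t, log_input = FALSE,
                               test = c("student", "welch")) {
  stopifnot(inherits(t, "condition_table"))
  test <- match.arg(test)
  a <- t$a
  b <- t$b
  if (!log_input) {
    if (any(a <= 0, na.rm = TRUE) || any(b <= 0, na.rm = TRUE)) {
      stop("raw intensities must be strictly positive for log2 transform; ",
           "use log_input = TRUE for log-scale data", call. = FALSE)
    }
    a <- log2(a)
    b <- log2(b)
  }
  p <- length(t$protein_ids)
  log2fc <- p_value <- rep(NA_real_, p)
  n_a <- n_b <- integer(p)
  n_skipped <- n_constant <- 0L
  for (i in seq_len(p)) {
    xa <- a[i, ][is.finite(a[i, ])]
    xb <- b[i, ][is.finite(b[i, ])]
    n_a[i] <- length(xa)
    n_b[i] <- length(xb)
    if (length(xa) < 2L || length(xb) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    log2fc[i] <- mean(xb) - mean(xa)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      n_constant <- n_constant + 1L
      p_value[i] <- 1
    } else {
      p_value[i] <- stats::t.test(xb, xa,
                                  var.equal = (test == "student"))$p.value
    }
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " protein(s) with < 2 finite replicates in a ",
            "condition reported with NA statistics", call. = FALSE)
  }
  if (n_constant > 0L) {
    warning(n_constant, " protein(s) with all-identical replicates in both ",
            "conditions; p reported as 1", call. = FALSE)
  }
  q_value <- rep(NA_real_, p)
  tested <- !is.na(p_value)
  q_value[tested] <- stats::p.adjust(p_value[tested], method = "BH")
  out <- data.frame(protein = t$protein_ids, log2fc = log2fc,
                    p_value = p_value, q_value = q_value,
                    n_a = n_a, n_b = n_b, stringsAsFactors = FALSE)
  structure(out, conditions = t$conditions,
            class = c("differential_table", "data.frame"))
}

#' @export
print.differential_table <- function(x, n = 10L, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("differential_table: %d proteins, log2fc = %s over %s\n",
              nrow(x), cond[2L], cond[1L]))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Group-level fold change for a named protein set
#'
#' Aggregates member log2 fold changes by their arithmetic mean and reports
#' the linear-scale fold `2^mean(log2fc)` — the geometric mean of member
#' folds, the natural aggregate for multiplicative abundance changes of a
#' complex's subunits.
#'
#' @param d A `differential_table`.
#' @param members Character vector of member protein ids.
#' @param label Group label.
#' @return A list of class `group_fold_change`: `label`, `members_used`,
#'   `members_skipped` (absent or untested), `member_log2fc`, `fold_change`.
#' @export
group_fold_change <- function(d, members, label = "") {
  stopifnot(inherits(d, "differential_table"))
  members <- unique(as.character(members))
  i <- match(members, d$protein)
  tested <- !is.na(i) & !is.na(d$log2fc[ifelse(is.na(i), 1L, i)])
  used <- members[tested]
  if (length(used) == 0L) {
    stop("no group member was tested", call. = FALSE)
  }
  lfc <- d$log2fc[match(used, d$protein)]
  names(lfc) <- used
  structure(list(label = as.character(label),
                 members_used = used,
                 members_skipped = setdiff(members, used),
                 member_log2fc = lfc,
                 fold_change = 2^mean(lfc)),
            class = "group_fold_change")
}

#' @export
print.group_fold_change <- function(x, ...) {
  cat(sprintf("group_fold_change%s: %.3f-fold over %d member(s)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$fold_change, length(x$members_used)))
  if (length(x$members_skipped)) {
    cat("  skipped:", paste(x$members_skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a differential table as TSV
#' @param d A `differential_table`.
#' @param path Output path.
#' @param full_precision Write full double precision.
#' @export
write_differential_table <- function(d, path, full_precision = FALSE) {
  stopifnot(inherits(d, "differential_table"))
  df <- as.data.frame(d)
  for (col in c("log2fc", "p_value", "q_value")) {
    df[[col]] <- format_num(df[[col]], full_precision = full_precision)
  }
  write_tsv_file(df, path)
}
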