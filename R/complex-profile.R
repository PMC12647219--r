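#' Subset a correlation matrix to a protein panel
#'
#' Restricts the matrix to a named panel (e.g. centromere proteins plus the
#' NDC80 outer-kinetochore complex), preserving entry values, the undefined
#' mask, and the panel's order. Absent ids are dropped with a warning.
#'
#' @param c A `correlation_matrix`.
#' @param panel Ordered character vector of protein ids.
#' @return A `correlation_matrix` over the present panel members, in panel
#'   order.
#' @export
subset_matrix <- function(c, panel) {
  stopifnot(inherits(c, "correlation_matrix"))
  panel <- as.character(panel)
  panel <- panel[!duplicated(panel)]
  present <- panel[panel %in% corr_ids(c)]
  absent <- setdiff(panel, present)
  if (length(absent) > 0L) {
    warning("panel ids absent from matrix: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  if (length(present) == 0L) {
    stop("no panel id present in the matrix", call. = FALSE)
  }
  correlation_matrix_obj(c$rho[present, present, drop = FALSE],
                         c$undefined_mask[present, present, drop = FALSE])
}

# Inclusive linear-interpolation quartiles (stats::quantile type 7).
quartile_summary <- function(x) {
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(lower = q[1L], median = q[2L], upper = q[3L])
}

#' Quartiles of one protein's correlations against all others
#'
#' Median and lower/upper quartiles over the protein's off-diagonal
#' correlations — the "range of all correlations" boxplot statistic used to
#' check that an outlier protein's lack of positive correlation with a
#' complex is not an artifact of a consistently narrow correlation range.
#'
#' @param c A `correlation_matrix` (of at least 2 proteins).
#' @param id Protein identifier.
#' @return A list with `lower`, `median`, `upper` and `n` (number of
#'   off-diagonal correlations summarized).
#' @export
correlation_range_summary <- function(c, id) {
  stopifnot(inherits(c, "correlation_matrix"))
  i <- match(id, corr_ids(c))
  if (is.na(i)) {
    stop("unknown protein id: ", id, call. = FALSE)
  }
  vals <- c$rho[i, -i]
  if (length(vals) == 0L) {
    stop("matrix has no off-diagonal entries", call. = FALSE)
  }
  c(quartile_summary(vals), list(n = length(vals)))
}

#' Quartiles of one protein's abundances, with missingness count
#'
#' Quartiles are computed after zero-imputation, so a protein quantified in
#' only a handful of samples has its median and quartiles driven to 0 —
#' exactly how sparsely detected centromere proteins present in published
#' abundance-range plots. The number of samples at zero or missing is
#' reported separately.
#'
#' @param m An [abundance_matrix].
#' @param id Protein identifier.
#' @return A list with `lower`, `median`, `upper`, `n_samples` and
#'   `n_zero_or_missing`.
#' @export
abundance_range_summary <- function(m, id) {
  stopifnot(inherits(m, "abundance_matrix"))
  i <- match(id, protein_ids(m))
  if (is.na(i)) {
    stop("unknown protein id: ", id, call. = FALSE)
  }
  row <- m$values[i, ]
  imputed <- ifelse(is.na(row), 0, row)
  c(quartile_summary(imputed),
    list(n_samples = length(row),
         n_zero_or_missing = sum(is.na(row) | row == 0)))
}

#' Profile a protein panel: sub-matrix plus per-protein ranges
#'
#' Bundles the panel's correlation sub-matrix with per-protein correlation
#' and abundance range summaries — the inputs of a complex-level heatmap
#' with accompanying range boxplots.
#'
#' @param c A `correlation_matrix`.
#' @param m The [abundance_matrix] the correlations came from.
#' @param panel Ordered character vector of panel protein ids.
#' @return A list of class `panel_profile`: `panel_ids` (present members in
#'   panel order), `sub_matrix`, `correlation_summary` and
#'   `abundance_summary` (data frames, one row per present panel protein).
#' @export
panel_profile <- function(c, m, panel) {
  stopifnot(inherits(c, "correlation_matrix"), inherits(m, "abundance_matrix"))
  sub <- subset_matrix(c, panel)
  ids <- corr_ids(sub)
  cs <- do.call(rbind, lapply(ids, function(id) {
    s <- correlation_range_summary(c, id)
    data.frame(protein = id, lower = s$lower, median = s$median,
               upper = s$upper, stringsAsFactors = FALSE)
  }))
  as_list <- lapply(ids, function(id) abundance_range_summary(m, id))
  ab <- do.call(rbind, lapply(seq_along(ids), function(k) {
    s <- as_list[[k]]
    data.frame(protein = ids[k], lower = s$lower, median = s$median,
               upper = s$upper, n_samples = s$n_samples,
               n_zero_or_missing = s$n_zero_or_missing,
               stringsAsFactors = FALSE)
  }))
  structure(list(panel_ids = ids, sub_matrix = sub,
                 correlation_summary = cs, abundance_summary = ab),
            class = "panel_profile")
}

#' @export
print.panel_profile <- function(x, ...) {
  cat(sprintf("panel_profile: %d panel proteins present\n",
              length(x$panel_ids)))
  invisible(x)
}

#' Read a protein panel file
#'
#' One protein id per line; blank lines and `#` comments ignored. The
#' bundled default panel (`system.file("extdata", "centromere_panel.txt",
#' package = "gbamine")`) lists the canonical centromere proteins (CENP-F
#' and CENP-J excluded) plus the four NDC80-complex members, as gene
#' symbols.
#'
#' @param path Panel file path.
#' @return Character vector of protein ids.
#' @export
read_panel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  check_ids(lines, "panel")
  lines
}
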