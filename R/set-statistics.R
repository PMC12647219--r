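#' Distribution summary
#'
#' A bag of correlation values with its exact sample median (mean of the two
#' central order statistics for even counts), as used for both the per-term
#' median distributions and the all-correlations background.
#'
#' @param values Numeric vector (may be empty).
#' @param label Free-text label.
#' @return An object of class `distribution_summary` with elements `values`,
#'   `median` (`NA` when empty) and `label`.
#' @export
distribution_summary <- function(values, label = "") {
  values <- as.numeric(values)
  med <- if (length(values) > 0L) stats::median(values) else NA_real_
  structure(list(values = values, median = med, label = as.character(label)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("distribution_summary%s: n = %d, median = %s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$values),
              if (is.na(x$median)) "NA" else format(x$median, digits = 4)))
  invisible(x)
}

# Off-diagonal (upper-triangle) correlations, each unordered pair once.
# exclude_undefined drops mask-flagged entries from the background.
background_values <- function(c, exclude_undefined = FALSE) {
  ut <- upper.tri(c$rho)
  if (exclude_undefined) ut <- ut & !c$undefined_mask
  c$rho[ut]
}

#' Background distribution of all correlations in a dataset
#'
#' All off-diagonal entries of the correlation matrix (upper triangle, each
#' unordered pair once; size p(p-1)/2). By default entries that were
#' undefined and set to 0 are included, matching a background of "all
#' correlations in the dataset"; `exclude_undefined = TRUE` drops them.
#'
#' @param c A `correlation_matrix`.
#' @param exclude_undefined Drop mask-flagged entries.
#' @return A [distribution_summary].
#' @export
background_distribution <- function(c, exclude_undefined = FALSE) {
  stopifnot(inherits(c, "correlation_matrix"))
  distribution_summary(background_values(c, exclude_undefined),
                       label = "background")
}

#' Median of within-term correlations for one annotation term
#'
#' Collects the correlation of every unordered pair of term members present
#' in the matrix (diagonal self-correlations never enter), drops pairs whose
#' correlation equals 1 — duplicate abundance profiles carry no association
#' information — and reports the median of the remainder. With
#' `exclusion = "near_one"`, values within 1e-12 of ±1 are also dropped, for
#' floating-point duplicates.
#'
#' @param c A `correlation_matrix`.
#' @param members Character vector of member protein ids (duplicates and
#'   ids absent from the matrix are tolerated).
#' @param term_id Optional term identifier carried through to the result.
#' @param exclusion `"exact"` (drop rho == 1, the default) or `"near_one"`
#'   (drop |rho| >= 1 - 1e-12).
#' @return A list of class `term_median_profile` with `term_id`,
#'   `n_members_present`, `n_pairs_used` and `median_rho` (`NA` when no
#'   pairs survive).
#' @export
term_median <- function(c, members, term_id = NA_character_,
                        exclusion = c("exact", "near_one")) {
  stopifnot(inherits(c, "correlation_matrix"))
  exclusion <- match.arg(exclusion)
  present <- intersect(unique(members), corr_ids(c))
  npresent <- length(present)
  if (npresent < 2L) {
    return(structure(list(term_id = term_id, n_members_present = npresent,
                          n_pairs_used = 0L, median_rho = NA_real_),
                     class = "term_median_profile"))
  }
  sub <- c$rho[present, present, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  keep <- if (exclusion == "exact") vals != 1 else abs(vals) < 1 - 1e-12
  vals <- vals[keep]
  structure(list(term_id = term_id, n_members_present = npresent,
                 n_pairs_used = length(vals),
                 median_rho = if (length(vals)) stats::median(vals) else NA_real_),
            class = "term_median_profile")
}

#' @export
print.term_median_profile <- function(x, ...) {
  cat(sprintf("term %s: %d members present, %d pairs, median rho = %s\n",
              x$term_id, x$n_members_present, x$n_pairs_used,
              if (is.na(x$median_rho)) "NA"
              else format(x$median_rho, digits = 4)))
  invisible(x)
}

#' Per-term medians for a whole annotation map
#'
#' Applies [term_median()] to every term and summarizes the distribution of
#' the defined medians — the statistic whose positive shift against the
#' background validates guilt-by-association: proteins sharing a functional
#' annotation correlate more strongly than bulk protein pairs.
#'
#' @param c A `correlation_matrix`.
#' @param ann An [annotation_map].
#' @param exclusion Passed to [term_median()].
#' @param exclude_undefined Passed to [background_distribution()].
#' @return A list of class `term_median_result`: `profiles` (data frame with
#'   one row per term: `term_id`, `n_members_present`, `n_pairs_used`,
#'   `median_rho`), `medians` (a [distribution_summary] over terms with a
#'   defined median) and `background` (a [distribution_summary]).
#' @export
all_term_medians <- function(c, ann, exclusion = c("exact", "near_one"),
                             exclude_undefined = FALSE) {
  stopifnot(inherits(c, "correlation_matrix"), inherits(ann, "annotation_map"))
  exclusion <- match.arg(exclusion)
  tm <- ann$term_to_members
  profs <- lapply(names(tm), function(t)
    term_median(c, tm[[t]], term_id = t, exclusion = exclusion))
  df <- data.frame(
    term_id = vapply(profs, `[[`, character(1L), "term_id"),
    n_members_present = vapply(profs, `[[`, integer(1L), "n_members_present"),
    n_pairs_used = vapply(profs, `[[`, integer(1L), "n_pairs_used"),
    median_rho = vapply(profs, `[[`, numeric(1L), "median_rho"),
    stringsAsFactors = FALSE
  )
  meds <- df$median_rho[!is.na(df$median_rho)]
  structure(list(
    profiles = df,
    medians = distribution_summary(meds, label = "term medians"),
    background = background_distribution(c, exclude_undefined)
  ), class = "term_median_result")
}

#' @export
print.term_median_result <- function(x, ...) {
  cat(sprintf(
    "term_median_result: %d terms (%d with a defined median)\n",
    nrow(x$profiles), length(x$medians$values)))
  cat(sprintf("  median of term medians: %s | background median: %s\n",
              format(x$medians$median, digits = 4),
              format(x$background$median, digits = 4)))
  invisible(x)
}

#' Pair-set correlation enrichment against the background
#'
#' Compares the correlations of a curated pair set (e.g. synthetic-lethal
#' partners) with the distribution of all correlations in the dataset. The
#' headline statistic is `shift`: set median minus background median; a
#' positive shift means the curated pairs co-vary more than bulk pairs.
#'
#' @param c A `correlation_matrix`.
#' @param ps A [pair_set].
#' @param exclude_undefined Passed to [background_distribution()].
#' @return A list of class `set_enrichment_result`: `set_distribution`,
#'   `background_distribution`, `shift` (`NA` when no pair is present),
#'   `n_pairs_used`, `n_pairs_absent`.
#' @export
pair_set_enrichment <- function(c, ps, exclude_undefined = FALSE) {
  stopifnot(inherits(c, "correlation_matrix"), inherits(ps, "pair_set"))
  ids <- corr_ids(c)
  ia <- match(ps$pairs$a, ids)
  ib <- match(ps$pairs$b, ids)
  present <- !is.na(ia) & !is.na(ib)
  vals <- c$rho[cbind(ia[present], ib[present])]
  setd <- distribution_summary(vals, label = ps$label)
  bg <- background_distribution(c, exclude_undefined)
  structure(list(
    set_distribution = setd,
    background_distribution = bg,
    shift = if (length(vals)) setd$median - bg$median else NA_real_,
    n_pairs_used = sum(present),
    n_pairs_absent = sum(!present)
  ), class = "set_enrichment_result")
}

#' @export
print.set_enrichment_result <- function(x, ...) {
  cat(sprintf(
    "set_enrichment_result: %d pairs in matrix (%d absent)\n  set median %s vs background %s -> shift %s\n",
    x$n_pairs_used, x$n_pairs_absent,
    format(x$set_distribution$median, digits = 4),
    format(x$background_distribution$median, digits = 4),
    if (is.na(x$shift)) "NA" else format(x$shift, digits = 4)))
  invisible(x)
}

#' Empirical null distribution of random-set medians
#'
#' Draws `n_draws` uniform random member sets of a given size and records
#' each set's [term_median()] — an empirical null for the median-of-medians
#' shift, extending the purely visual set-vs-background comparison.
#'
#' @param c A `correlation_matrix`.
#' @param set_size Members per random set (>= 2, <= protein count).
#' @param n_draws Number of random sets (>= 1).
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A [distribution_summary] of the `n_draws` medians (draws with no
#'   usable pair are recorded as `NA` and excluded from the summary median).
#' @export
random_set_null <- function(c, set_size, n_draws, seed) {
  stopifnot(inherits(c, "correlation_matrix"),
            set_size >= 2L, n_draws >= 1L)
  ids <- corr_ids(c)
  if (set_size > length(ids)) {
    stop("set_size exceeds protein count", call. = FALSE)
  }
  meds <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    term_median(c, sample(ids, set_size))$median_rho
  }, numeric(1L)))
  distribution_summary(meds[!is.na(meds)],
                       label = sprintf("random sets (size %d)", set_size))
}

#' Write per-term median profiles as TSV
#' @param res A `term_median_result`.
#' @param path Output path.
#' @export
write_term_medians <- function(res, path) {
  stopifnot(inherits(res, "term_median_result"))
  df <- res$profiles
  df$median_rho <- format_num(df$median_rho)
  write_tsv_file(df, path)
}
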