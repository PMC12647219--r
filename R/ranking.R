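#' Ranked association list for a query protein
#'
#' Orders every protein in a correlation matrix by descending correlation
#' with a query protein — the guilt-by-association ranking. The query heads
#' its own list at rank 1 with rho = 1 (its diagonal self-correlation);
#' ties are broken lexicographically by partner id so results are
#' deterministic. Set `include_query = FALSE` for partner-only ranks (the
#' two conventions differ by exactly 1 for every partner).
#'
#' @param c A `correlation_matrix`.
#' @param query_id Identifier of the query protein (must be present).
#' @param include_query Keep the query itself at rank 1? Default `TRUE`.
#' @param dataset_label Label stored on the result.
#' @return An object of class `ranked_associations`: a data frame with
#'   columns `rank`, `protein`, `rho` and attributes `query_id` and
#'   `dataset_label`.
#' @export
rank_associations <- function(c, query_id, include_query = TRUE,
                              dataset_label = "") {
  stopifnot(inherits(c, "correlation_matrix"))
  ids <- corr_ids(c)
  qi <- match(query_id, ids)
  if (is.na(qi)) {
    stop("unknown query id: ", query_id, call. = FALSE)
  }
  rho <- c$rho[qi, ]
  partners <- ids
  if (!include_query) {
    rho <- rho[-qi]
    partners <- partners[-qi]
  }
  ord <- order(-rho, partners, method = "radix")
  if (include_query) {
    # the query is rank 1 by convention even if a partner ties at rho = 1
    # and sorts lexicographically earlier
    qpos <- which(partners[ord] == query_id)
    if (qpos != 1L) ord <- c(ord[qpos], ord[-qpos])
  }
  out <- data.frame(rank = seq_along(ord),
                    protein = partners[ord],
                    rho = unname(rho[ord]),
                    stringsAsFactors = FALSE)
  structure(out, query_id = query_id, dataset_label = dataset_label,
            class = c("ranked_associations", "data.frame"))
}

#' @export
print.ranked_associations <- function(x, n = 10L, ...) {
  cat(sprintf("ranked_associations for query '%s'%s: %d proteins\n",
              attr(x, "query_id"),
              if (nzchar(attr(x, "dataset_label")))
                paste0(" [", attr(x, "dataset_label"), "]") else "",
              nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Top-k prefix of a ranked association list
#'
#' @param list A `ranked_associations` object.
#' @param k Positive integer, at most the list length.
#' @return The first `k` entries, ranks preserved, same class/attributes.
#' @export
top_k <- function(list, k) {
  stopifnot(inherits(list, "ranked_associations"))
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > nrow(list)) {
    stop("k must be in 1..", nrow(list), call. = FALSE)
  }
  out <- list[seq_len(k), , drop = FALSE]
  attributes(out)[c("query_id", "dataset_label", "class")] <-
    attributes(list)[c("query_id", "dataset_label", "class")]
  out
}

#' Rank of a named protein in an association list
#'
#' @param list A `ranked_associations` object.
#' @param target_id Protein identifier present in the list.
#' @return Its 1-based rank under the list's tie rule.
#' @export
rank_of <- function(list, target_id) {
  stopifnot(inherits(list, "ranked_associations"))
  i <- match(target_id, list$protein)
  if (is.na(i)) {
    stop("unknown target id: ", target_id, call. = FALSE)
  }
  list$rank[i]
}

#' Shared partners in the top-k of two ranked lists
#'
#' Intersection of the k-prefixes of two association lists (e.g. the same
#' query ranked in two independent proteome datasets), excluding the query
#' proteins themselves — the cross-dataset reproducibility check.
#'
#' @param a,b `ranked_associations` objects (possibly over different
#'   protein universes).
#' @param k Prefix length applied to both lists (capped at each list's
#'   length).
#' @return Character vector of shared partner ids, sorted.
#' @export
top_k_overlap <- function(a, b, k) {
  stopifnot(inherits(a, "ranked_associations"),
            inherits(b, "ranked_associations"))
  pa <- top_k(a, min(k, nrow(a)))$protein
  pb <- top_k(b, min(k, nrow(b)))$protein
  shared <- intersect(pa, pb)
  sort(setdiff(shared, c(attr(a, "query_id"), attr(b, "query_id"))))
}

#' Write a ranked association list as TSV
#' @param list A `ranked_associations` object.
#' @param path Output path.
#' @param full_precision Write full double precision.
#' @export
write_ranked_list <- function(list, path, full_precision = FALSE) {
  stopifnot(inherits(list, "ranked_associations"))
  df <- data.frame(rank = list$rank, protein = list$protein,
                   rho = format_num(list$rho, full_precision = full_precision),
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
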