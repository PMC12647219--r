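#' Build a validated pipeline run configuration
#'
#' Collects everything one guilt-by-association run needs: the abundance
#' matrix, the query proteins to rank, and optional annotation / pair-set /
#' panel inputs. All referenced paths are checked at validation time.
#'
#' @param abundance Path to the abundance matrix (TSV/CSV).
#' @param out_dir Output directory (created if absent).
#' @param queries Character vector of query protein ids to rank.
#' @param k Top-k prefix length written per query (default 25).
#' @param annotation Optional path to a flat protein/term annotation TSV.
#' @param pairs Optional path to a pair-list TSV.
#' @param reliability_filter Optional evidence labels to keep from `pairs`.
#' @param panel Optional path to a panel file (see [read_panel()]).
#' @param exclude Protein ids dropped from the panel before profiling
#'   (e.g. complex members deliberately excluded from a heatmap).
#' @param missing_tokens Missing-value markers in the abundance file.
#' @param rows_are_proteins Orientation of the abundance file.
#' @param include_query Keep each query at rank 1 of its own list.
#' @param dataset_label Label recorded on ranked lists.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(abundance, out_dir, queries = character(), k = 25L,
                       annotation = NULL, pairs = NULL,
                       reliability_filter = NULL, panel = NULL,
                       exclude = character(),
                       missing_tokens = c("", "NA", "NaN", "null"),
                       rows_are_proteins = TRUE, include_query = TRUE,
                       dataset_label = "") {
  cfg <- list(abundance = abundance, out_dir = out_dir,
              queries = as.character(queries), k = as.integer(k),
              annotation = annotation, pairs = pairs,
              reliability_filter = reliability_filter, panel = panel,
              exclude = as.character(exclude),
              missing_tokens = missing_tokens,
              rows_are_proteins = isTRUE(rows_are_proteins),
              include_query = isTRUE(include_query),
              dataset_label = as.character(dataset_label))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$k < 1L) stop("config: k must be >= 1", call. = FALSE)
  for (field in c("abundance", "annotation", "pairs", "panel")) {
    path <- cfg[[field]]
    if (!is.null(path) && !file.exists(path)) {
      stop("config: ", field, " path does not exist: ", path, call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`) whose keys match the
#'   arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

#' Run the full guilt-by-association pipeline
#'
#' Executes impute -> correlate -> rank/top-k (per query) -> term medians ->
#' pair-set enrichment -> panel profile, writing every result as TSV under
#' the configured output directory plus a `manifest.json` recording package
#' and R versions, a hash of the configuration, and an MD5 checksum per
#' output file. Identical configuration and inputs produce byte-identical
#' outputs. Any stage failure aborts with a stage-named error before partial
#' results of that stage are written (queries are validated before any
#' ranked list is written).
#'
#' @param config A `run_config` (or a path accepted by [read_run_config()]).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  m <- stage("read", read_abundance_matrix(
    config$abundance, missing_tokens = config$missing_tokens,
    rows_are_proteins = config$rows_are_proteins,
    source_label = config$dataset_label))

  cmat <- stage("correlate", correlation_matrix(m))
  cpath <- file.path(config$out_dir, "correlation_matrix.tsv")
  write_correlation_matrix(cmat, cpath)
  outputs <- c(outputs, cpath)
  if (any(cmat$undefined_mask)) {
    outputs <- c(outputs, paste0(cpath, ".mask.tsv"))
  }

  stage("rank", {
    missing_q <- setdiff(config$queries, corr_ids(cmat))
    if (length(missing_q) > 0L) {
      stop("unknown query id: ", paste(missing_q, collapse = ", "),
           call. = FALSE)
    }
  })
  for (q in config$queries) {
    rl <- stage("rank", rank_associations(
      cmat, q, include_query = config$include_query,
      dataset_label = config$dataset_label))
    full_path <- file.path(config$out_dir, paste0("ranked_", q, ".tsv"))
    write_ranked_list(rl, full_path)
    top_path <- file.path(config$out_dir,
                          paste0("top", config$k, "_", q, ".tsv"))
    write_ranked_list(top_k(rl, min(config$k, nrow(rl))), top_path)
    outputs <- c(outputs, full_path, top_path)
  }

  if (!is.null(config$annotation)) {
    ann <- stage("annotation", read_annotation_map(config$annotation))
    res <- stage("term-medians", all_term_medians(cmat, ann))
    tpath <- file.path(config$out_dir, "term_medians.tsv")
    write_term_medians(res, tpath)
    spath <- file.path(config$out_dir, "term_medians_summary.tsv")
    write_tsv_file(data.frame(
      statistic = c("median_of_term_medians", "background_median"),
      value = format_num(c(res$medians$median, res$background$median))
    ), spath)
    outputs <- c(outputs, tpath, spath)
  }

  if (!is.null(config$pairs)) {
    ps <- stage("pairs", read_pair_set(
      config$pairs, reliability_filter = config$reliability_filter))
    enr <- stage("pairset-enrich", pair_set_enrichment(cmat, ps))
    epath <- file.path(config$out_dir, "pairset_enrichment.tsv")
    write_tsv_file(data.frame(
      statistic = c("set_median", "background_median", "shift",
                    "n_pairs_used", "n_pairs_absent"),
      value = c(format_num(c(enr$set_distribution$median,
                             enr$background_distribution$median,
                             enr$shift)),
                enr$n_pairs_used, enr$n_pairs_absent)
    ), epath)
    outputs <- c(outputs, epath)
  }

  if (!is.null(config$panel)) {
    panel <- stage("panel", setdiff(read_panel(config$panel), config$exclude))
    prof <- stage("panel", panel_profile(cmat, m, panel))
    sub_path <- file.path(config$out_dir, "panel_matrix.tsv")
    write_correlation_matrix(prof$sub_matrix, sub_path)
    outputs <- c(outputs, sub_path)
    if (any(prof$sub_matrix$undefined_mask)) {
      outputs <- c(outputs, paste0(sub_path, ".mask.tsv"))
    }
    cs <- prof$correlation_summary
    for (col in c("lower", "median", "upper")) cs[[col]] <- format_num(cs[[col]])
    cs_path <- file.path(config$out_dir, "panel_correlation_ranges.tsv")
    write_tsv_file(cs, cs_path)
    ab <- prof$abundance_summary
    for (col in c("lower", "median", "upper")) ab[[col]] <- format_num(ab[[col]])
    ab_path <- file.path(config$out_dir, "panel_abundance_ranges.tsv")
    write_tsv_file(ab, ab_path)
    outputs <- c(outputs, cs_path, ab_path)
  }

  manifest <- list(
    package = "gbamine",
    package_version = as.character(utils::packageVersion("gbamine")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(config),
    outputs = as.list(tools::md5sum(outputs))
  )
  names(manifest$outputs) <- basename(outputs)
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# MD5 of the canonical JSON serialization of the configuration.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}
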