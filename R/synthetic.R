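#' Specification of a synthetic proteome cohort
#'
#' Describes a simulated wide abundance matrix with planted correlated
#' modules and detection-limit missingness. Log2 intensities follow a
#' single-factor-per-module model: members of a module share one latent
#' sample factor with a loading calibrated so the population Spearman
#' correlation between members approximates the requested `rho` (via the
#' Gaussian rank-correlation relation `rho_S = (6/pi) * asin(rho_P / 2)`,
#' i.e. `rho_P = 2 * sin(pi * rho_S / 6)`); all other proteins are
#' independent. Missingness is abundance-dependent — the probability that a
#' cell is missing is a logistic function of its true log2 abundance, so
#' low-abundance proteins are censored more often, reproducing sparsely
#' detected proteins whose summaries collapse to zero.
#'
#' The defaults describe the package's reference validation cohort:
#' 1000 proteins by 500 samples with one size-8 module at target Spearman
#' 0.7 and a 20 percent global missing rate.
#'
#' @param n_proteins,n_samples Matrix dimensions.
#' @param modules List of `list(size =, rho =)` planted modules; sizes must
#'   sum to at most `n_proteins`, `rho` in `[0, 1)`. Module members occupy
#'   the leading protein ids, in order.
#' @param baseline_log_mean,baseline_log_sd Per-protein baseline log2
#'   intensity distribution (log2 units; defaults emulate MS intensity
#'   scales).
#' @param missing_rate Global expected fraction of missing cells, in
#'   `[0, 1)`.
#' @param detection_slope Logistic slope (per standardized log2 abundance)
#'   of the missingness model; 0 gives abundance-independent missingness.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_proteins = 1000L, n_samples = 500L,
                        modules = list(list(size = 8L, rho = 0.7)),
                        baseline_log_mean = 14, baseline_log_sd = 2,
                        missing_rate = 0.2, detection_slope = 1,
                        seed = 1L) {
  stopifnot(n_proteins >= 1L, n_samples >= 2L,
            baseline_log_sd >= 0, missing_rate >= 0, missing_rate < 1,
            detection_slope >= 0)
  modules <- lapply(modules, function(m) {
    stopifnot(!is.null(m$size), !is.null(m$rho),
              m$size >= 2L, m$rho >= 0, m$rho < 1)
    list(size = as.integer(m$size), rho = as.numeric(m$rho))
  })
  if (sum(vapply(modules, `[[`, integer(1L), "size")) > n_proteins) {
    stop("module sizes exceed n_proteins", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples = as.integer(n_samples),
                 modules = modules,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 missing_rate = missing_rate,
                 detection_slope = detection_slope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic abundance cohort
#'
#' Draws the cohort described by a [cohort_spec()] and returns both the
#' abundance matrix (intensities `2^x`, missing cells `NA`) and the ground
#' truth needed to build matched annotation maps and pair sets.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `matrix` (an [abundance_matrix]) and
#'   `truth` (class `cohort_truth`: `protein_ids`, `module` — integer
#'   module index per protein, 0 for independent proteins — and the spec's
#'   `modules` list).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$n_proteins
  n <- spec$n_samples
  ids <- sprintf("P%04d", seq_len(p))
  module <- integer(p)
  offset <- 0L
  for (k in seq_along(spec$modules)) {
    sz <- spec$modules[[k]]$size
    module[(offset + 1L):(offset + sz)] <- k
    offset <- offset + sz
  }
  x <- with_seed(spec$seed, {
    baseline <- stats::rnorm(p, spec$baseline_log_mean, spec$baseline_log_sd)
    eps <- matrix(stats::rnorm(p * n), p, n)
    s <- eps
    for (k in seq_along(spec$modules)) {
      rho_s <- spec$modules[[k]]$rho
      # Gaussian copula: Pearson loading^2 giving the target Spearman
      rho_p <- 2 * sin(pi * rho_s / 6)
      lambda <- sqrt(rho_p)
      f <- stats::rnorm(n)
      idx <- which(module == k)
      s[idx, ] <- lambda * rep(f, each = length(idx)) +
        sqrt(1 - rho_p) * eps[idx, , drop = FALSE]
    }
    x <- baseline + s
    if (spec$missing_rate > 0) {
      z <- (x - mean(x)) / stats::sd(x)
      slope <- spec$detection_slope
      alpha <- stats::uniroot(
        function(a) mean(stats::plogis(a - slope * z)) - spec$missing_rate,
        interval = c(-50, 50), tol = 1e-10)$root
      pmiss <- stats::plogis(alpha - slope * z)
      x[stats::runif(p * n) < pmiss] <- NA_real_
    }
    x
  })
  values <- 2^x
  dimnames(values) <- list(ids, sprintf("S%04d", seq_len(n)))
  truth <- structure(list(protein_ids = ids, module = module,
                          modules = spec$modules, seed = spec$seed),
                     class = "cohort_truth")
  list(matrix = abundance_matrix(values, source_label = "synthetic cohort"),
       truth = truth)
}

#' Generate an annotation map matched to a cohort
#'
#' One coherent term per planted module (ids `MOD:<k>`, members exactly the
#' module members) plus `n_random_terms` terms of uniformly sampled members
#' (ids `RND:<j>`) — the coherent/random contrast used to validate the
#' median-of-correlations statistic.
#'
#' @param truth A `cohort_truth` from [generate_cohort()].
#' @param n_random_terms Number of random terms.
#' @param random_term_size Members per random term.
#' @param seed Integer seed.
#' @return An [annotation_map].
#' @export
generate_annotation <- function(truth, n_random_terms = 0L,
                                random_term_size = 8L, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  terms <- list()
  for (k in seq_along(truth$modules)) {
    terms[[sprintf("MOD:%04d", k)]] <- truth$protein_ids[truth$module == k]
  }
  if (n_random_terms > 0L) {
    stopifnot(random_term_size >= 2L,
              random_term_size <= length(truth$protein_ids))
    rnd <- with_seed(seed, lapply(seq_len(n_random_terms), function(j) {
      sample(truth$protein_ids, random_term_size)
    }))
    names(rnd) <- sprintf("RND:%04d", seq_len(n_random_terms))
    terms <- c(terms, rnd)
  }
  annotation_map(terms)
}

#' Generate a pair set matched to a cohort
#'
#' Samples `n_planted` unordered pairs from within planted modules (truly
#' correlated pairs, evidence `"planted"`) and `n_null` pairs between
#' independent proteins (evidence `"null"`).
#'
#' @param truth A `cohort_truth` from [generate_cohort()].
#' @param n_planted,n_null Pair counts.
#' @param seed Integer seed.
#' @return A [pair_set] with an `evidence` column recording the truth class.
#' @export
generate_pair_set <- function(truth, n_planted, n_null, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"), n_planted >= 0L, n_null >= 0L)
  within <- do.call(rbind, lapply(seq_along(truth$modules), function(k) {
    ids <- truth$protein_ids[truth$module == k]
    if (length(ids) < 2L) return(NULL)
    t(utils::combn(ids, 2L))
  }))
  n_within <- if (is.null(within)) 0L else nrow(within)
  if (n_planted > n_within) {
    stop("insufficient within-module pairs: ", n_within, " available",
         call. = FALSE)
  }
  indep <- truth$protein_ids[truth$module == 0L]
  with_seed(seed, {
    planted <- if (n_planted > 0L) {
      within[sample(n_within, n_planted), , drop = FALSE]
    } else {
      matrix(character(), 0L, 2L)
    }
    nulls <- matrix(character(), 0L, 2L)
    if (n_null > 0L) {
      if (length(indep) < 2L) {
        stop("not enough independent proteins for null pairs", call. = FALSE)
      }
      seen <- character()
      while (nrow(nulls) < n_null) {
        a <- sample(indep, n_null)
        b <- sample(indep, n_null)
        ok <- a != b
        key <- paste(pmin(a, b), pmax(a, b))
        ok <- ok & !duplicated(key) & !(key %in% seen)
        nulls <- rbind(nulls, cbind(a[ok], b[ok]))
        seen <- c(seen, key[ok])
        if (nrow(nulls) > n_null) nulls <- nulls[seq_len(n_null), , drop = FALSE]
      }
    }
    pair_set(c(planted[, 1L], nulls[, 1L]),
             c(planted[, 2L], nulls[, 2L]),
             label = "synthetic",
             evidence = c(rep("planted", nrow(planted)),
                          rep("null", nrow(nulls))))
  })
}

#' Generate a two-condition depletion experiment
#'
#' Log2 replicate intensities are drawn around per-protein baselines with
#' independent Gaussian noise; condition B is shifted by `log2(fold)` for
#' planted proteins. The returned table is on the log2 scale — pass
#' `log_input = TRUE` to [differential_table()].
#'
#' @param n_proteins Number of proteins (ids `P0001`...).
#' @param n_replicates Replicates per condition (default 4, the replicated
#'   chromosome-proteome design).
#' @param planted Named numeric vector of linear fold changes (condition B
#'   over A) for planted proteins; all folds must be positive. Unnamed
#'   proteins have true fold 1.
#' @param sigma Log2-scale replicate noise standard deviation.
#' @param baseline_log_mean,baseline_log_sd Baseline log2 intensity
#'   distribution.
#' @param conditions Length-2 condition names (A = reference first).
#' @param seed Integer seed.
#' @return A [condition_table] of log2 intensities.
#' @export
generate_depletion <- function(n_proteins, n_replicates = 4L,
                               planted = numeric(), sigma = 0.2,
                               baseline_log_mean = 14, baseline_log_sd = 2,
                               conditions = c("wt", "depleted"), seed = 1L) {
  stopifnot(n_proteins >= 1L, n_replicates >= 2L, sigma >= 0)
  if (length(planted) > 0L) {
    if (is.null(names(planted)) || any(!nzchar(names(planted)))) {
      stop("`planted` must be a named vector of folds", call. = FALSE)
    }
    if (any(planted <= 0)) {
      stop("planted folds must be positive", call. = FALSE)
    }
  }
  ids <- sprintf("P%04d", seq_len(n_proteins))
  unknown <- setdiff(names(planted), ids)
  if (length(unknown) > 0L) {
    stop("planted ids not in cohort: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  shift <- rep(0, n_proteins)
  shift[match(names(planted), ids)] <- log2(planted)
  with_seed(seed, {
    baseline <- stats::rnorm(n_proteins, baseline_log_mean, baseline_log_sd)
    a <- baseline + matrix(stats::rnorm(n_proteins * n_replicates, 0, sigma),
                           n_proteins, n_replicates)
    b <- baseline + shift +
      matrix(stats::rnorm(n_proteins * n_replicates, 0, sigma),
             n_proteins, n_replicates)
    condition_table(ids, a, b, conditions = conditions)
  })
}
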