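test_that("cohort specs validate their structural invariants", {
  expect_error(cohort_spec(n_proteins = 10,
                           modules = list(list(size = 6, rho = 0.5),
                                          list(size = 6, rho = 0.5))),
               "exceed n_proteins")
  expect_error(cohort_spec(modules = list(list(size = 4, rho = 1))))
  expect_error(cohort_spec(missing_rate = 1))
  spec <- cohort_spec(n_proteins = 20, n_samples = 10, modules = list(),
                      missing_rate = 0)
  expect_s3_class(spec, "cohort_spec")
})

test_that("module-free, missingness-free cohorts are complete and independent", {
  spec <- cohort_spec(n_proteins = 50, n_samples = 40, modules = list(),
                      missing_rate = 0, seed = 100)
  co <- generate_cohort(spec)
  expect_identical(n_missing(co$matrix), 0L)
  expect_identical(dim(co$matrix$values), c(50L, 40L))
  expect_true(all(co$matrix$values > 0))
  expect_identical(co$truth$module, rep(0L, 50))
})

test_that("generation is fully reproducible from the seed", {
  spec <- cohort_spec(n_proteins = 40, n_samples = 30, seed = 7,
                      modules = list(list(size = 5, rho = 0.5)),
                      missing_rate = 0.2)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  ann1 <- generate_annotation(a$truth, n_random_terms = 5, seed = 8)
  ann2 <- generate_annotation(a$truth, n_random_terms = 5, seed = 8)
  expect_identical(ann1$term_to_members, ann2$term_to_members)

  ps1 <- generate_pair_set(a$truth, 5, 5, seed = 9)
  ps2 <- generate_pair_set(a$truth, 5, 5, seed = 9)
  expect_identical(ps1$pairs, ps2$pairs)

  ct1 <- generate_depletion(20, 4, sigma = 0.1, seed = 10)
  ct2 <- generate_depletion(20, 4, sigma = 0.1, seed = 10)
  expect_identical(ct1$a, ct2$a)
  expect_identical(ct1$b, ct2$b)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_spec(n_proteins = 10, n_samples = 5,
                                        modules = list(), missing_rate = 0.1,
                                        seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("the module loading calibration hits the target Spearman", {
  spec <- cohort_spec(n_proteins = 30, n_samples = 500,
                      modules = list(list(size = 10, rho = 0.7)),
                      missing_rate = 0, seed = 104)
  co <- generate_cohort(spec)
  cm <- correlation_matrix(co$matrix)
  idx <- which(co$truth$module == 1L)
  within <- cm$rho[idx, idx][upper.tri(diag(length(idx)))]
  expect_gt(mean(within), 0.62)
  expect_lt(mean(within), 0.78)
})

test_that("global missingness rate is honored and abundance-dependent", {
  spec <- cohort_spec(n_proteins = 300, n_samples = 100, modules = list(),
                      missing_rate = 0.2, detection_slope = 2, seed = 105)
  co <- generate_cohort(spec)
  rate <- n_missing(co$matrix) / (300 * 100)
  expect_gt(rate, 0.17)
  expect_lt(rate, 0.23)
  # low-baseline proteins must be censored more often than high-baseline ones
  miss_per_protein <- rowMeans(is.na(co$matrix$values))
  med <- apply(co$matrix$values, 1, median, na.rm = TRUE)
  expect_lt(cor(med, miss_per_protein, method = "spearman"), -0.5)
})

test_that("steep detection slopes produce near-fully-censored proteins", {
  spec <- cohort_spec(n_proteins = 400, n_samples = 120, modules = list(),
                      baseline_log_sd = 3, missing_rate = 0.5,
                      detection_slope = 4, seed = 106)
  co <- generate_cohort(spec)
  miss_per_protein <- rowMeans(is.na(co$matrix$values))
  # sparsely detected proteins exist, exercising the undefined-rho policy
  expect_gt(sum(miss_per_protein > 0.9), 0)
})

test_that("annotation generation mirrors modules and samples random terms", {
  spec <- cohort_spec(n_proteins = 60, n_samples = 20,
                      modules = list(list(size = 6, rho = 0.5),
                                     list(size = 4, rho = 0.3)),
                      missing_rate = 0, seed = 107)
  truth <- generate_cohort(spec)$truth
  ann <- generate_annotation(truth, n_random_terms = 0)
  expect_identical(length(ann$term_to_members), 2L)
  expect_setequal(ann$term_to_members[["MOD:0001"]], sprintf("P%04d", 1:6))
  expect_setequal(ann$term_to_members[["MOD:0002"]], sprintf("P%04d", 7:10))

  ann2 <- generate_annotation(truth, n_random_terms = 5,
                              random_term_size = 3, seed = 108)
  expect_identical(length(ann2$term_to_members), 7L)
  expect_true(all(lengths(ann2$term_to_members[3:7]) == 3L))
})

test_that("pair sets respect truth classes and available module pairs", {
  spec <- cohort_spec(n_proteins = 40, n_samples = 20,
                      modules = list(list(size = 5, rho = 0.5)),
                      missing_rate = 0, seed = 109)
  truth <- generate_cohort(spec)$truth
  module_ids <- sprintf("P%04d", 1:5)

  all_planted <- generate_pair_set(truth, n_planted = 10, n_null = 0, seed = 1)
  expect_identical(n_pairs(all_planted), 10L)  # every pair of a size-5 module
  expect_true(all(c(all_planted$pairs$a, all_planted$pairs$b) %in% module_ids))

  expect_error(generate_pair_set(truth, n_planted = 11, n_null = 0, seed = 1),
               "insufficient within-module pairs")

  nulls <- generate_pair_set(truth, n_planted = 0, n_null = 30, seed = 2)
  expect_identical(n_pairs(nulls), 30L)
  expect_true(all(nulls$pairs$evidence == "null"))
  expect_false(any(c(nulls$pairs$a, nulls$pairs$b) %in% module_ids))
})

test_that("depletion folds shift condition B on the log2 scale", {
  # fold 1 everywhere, sigma 0: identical conditions
  ct <- generate_depletion(10, 3, sigma = 0, seed = 110)
  expect_identical(ct$a, ct$b)
  # sigma 0, fold 2: log2fc exactly 1
  ct2 <- generate_depletion(10, 3, planted = c(P0004 = 2), sigma = 0,
                            seed = 111)
  d <- suppressWarnings(differential_table(ct2, log_input = TRUE))
  expect_identical(d$log2fc[d$protein == "P0004"], 1)
  expect_identical(sum(d$log2fc != 0), 1L)
  expect_error(generate_depletion(10, 3, planted = c(P0001 = -2), seed = 1),
               "positive")
  expect_error(generate_depletion(10, 3, planted = c(Z9 = 2), seed = 1),
               "not in cohort")
})

test_that("end-to-end: planted partners dominate the query's top ranks", {
  spec <- cohort_spec(n_proteins = 400, n_samples = 300,
                      modules = list(list(size = 8, rho = 0.7)),
                      missing_rate = 0.2, detection_slope = 1, seed = 112)
  co <- generate_cohort(spec)
  cm <- correlation_matrix(co$matrix)
  top10 <- top_k(rank_associations(cm, "P0001"), 10)$protein
  expect_identical(sum(sprintf("P%04d", 2:8) %in% top10), 7L)
})
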