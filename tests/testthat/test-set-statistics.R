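make_term_matrix <- function(ab, ac, bc) {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- ab
  rho[1, 3] <- rho[3, 1] <- ac
  rho[2, 3] <- rho[3, 2] <- bc
  toy_correlation(rho, ids = c("A", "B", "C"))
}

test_that("term_median takes each unordered member pair once", {
  cm <- make_term_matrix(0.2, 0.4, 0.6)
  prof <- term_median(cm, c("A", "B", "C"), term_id = "T1")
  expect_identical(prof$n_members_present, 3L)
  expect_identical(prof$n_pairs_used, 3L)
  expect_equal(prof$median_rho, 0.4)
  # member order / duplicate listings are irrelevant
  prof2 <- term_median(cm, c("C", "A", "B", "A", "C"))
  expect_equal(prof2$median_rho, prof$median_rho)
  expect_identical(prof2$n_pairs_used, prof$n_pairs_used)
})

test_that("pairs with correlation exactly 1 are excluded", {
  cm <- make_term_matrix(1, 0.1, 0.3)
  prof <- term_median(cm, c("A", "B", "C"))
  expect_identical(prof$n_pairs_used, 2L)
  expect_equal(prof$median_rho, 0.2)
  # near-one widening drops floating-point duplicates too
  cm2 <- make_term_matrix(1 - 1e-14, 0.1, 0.3)
  expect_identical(term_median(cm2, c("A", "B", "C"))$n_pairs_used, 3L)
  expect_identical(
    term_median(cm2, c("A", "B", "C"), exclusion = "near_one")$n_pairs_used, 2L)
})

test_that("degenerate member sets yield an absent median", {
  cm <- make_term_matrix(0.2, 0.4, 0.6)
  for (members in list("A", c("X", "Y"), character(0))) {
    prof <- term_median(cm, members)
    expect_identical(prof$n_pairs_used, 0L)
    expect_true(is.na(prof$median_rho))
  }
})

test_that("all_term_medians summarizes terms and the global background", {
  cm <- make_term_matrix(0.1, 0.1, 0.3)
  ann <- annotation_map(list(T1 = c("A", "B"), T2 = c("B", "C"),
                             S1 = "A", T3 = c("A", "X")))
  res <- all_term_medians(cm, ann)
  # all four terms profiled; S1 (singleton) and T3 (one member present)
  # yield absent medians and are excluded from the distribution
  expect_identical(nrow(res$profiles), 4L)
  expect_equal(sort(res$medians$values), c(0.1, 0.3))
  expect_equal(res$medians$median, 0.2)
  # background: all p(p-1)/2 off-diagonal entries, diagonal excluded
  expect_identical(length(res$background$values), 3L)
  expect_equal(res$background$median, 0.1)

  only_singletons <- annotation_map(list(S1 = "A", S2 = "B"))
  res2 <- all_term_medians(cm, only_singletons)
  expect_identical(length(res2$medians$values), 0L)
  expect_true(is.na(res2$medians$median))
})

test_that("background size is p(p-1)/2 and respects the undefined flag", {
  v <- rbind(P1 = c(1, 2, 3, 4), P2 = c(3, 3, 3, 3), P3 = c(2, 4, 1, 3),
             P4 = c(5, 1, 2, 4))
  colnames(v) <- sprintf("s%d", 1:4)
  cm <- correlation_matrix(abundance_matrix(v))
  bg <- background_distribution(cm)
  expect_identical(length(bg$values), 6L)
  bg2 <- background_distribution(cm, exclude_undefined = TRUE)
  expect_identical(length(bg2$values), 3L)  # P2 is constant: 3 pairs masked
})

test_that("pair_set_enrichment reports shift and absent pairs", {
  cm <- make_term_matrix(0.4, 0.0, -0.2)
  ps <- pair_set(c("A", "A", "Q"), c("B", "Z", "R"))
  enr <- pair_set_enrichment(cm, ps)
  expect_identical(enr$n_pairs_used, 1L)
  expect_identical(enr$n_pairs_absent, 2L)
  expect_equal(enr$set_distribution$median, 0.4)
  expect_equal(enr$shift, 0.4 - enr$background_distribution$median)

  empty <- pair_set()
  enr0 <- pair_set_enrichment(cm, empty)
  expect_identical(length(enr0$set_distribution$values), 0L)
  expect_true(is.na(enr0$shift))
})

test_that("planted pair sets shift positive; null pairs do not", {
  spec <- cohort_spec(n_proteins = 300, n_samples = 250,
                      modules = list(list(size = 10, rho = 0.6)),
                      missing_rate = 0, seed = 61)
  co <- generate_cohort(spec)
  cm <- correlation_matrix(co$matrix)
  ps <- generate_pair_set(co$truth, n_planted = 30, n_null = 100, seed = 62)
  planted <- ps$pairs$evidence == "planted"
  enr_p <- pair_set_enrichment(cm, pair_set(ps$pairs$a[planted],
                                            ps$pairs$b[planted]))
  enr_n <- pair_set_enrichment(cm, pair_set(ps$pairs$a[!planted],
                                            ps$pairs$b[!planted]))
  expect_gt(enr_p$shift, 0.3)
  expect_lt(abs(enr_n$shift), 0.05)
})

test_that("pair-set shift grows with planted intra-module correlation", {
  shifts <- vapply(c(0.2, 0.5, 0.8), function(r) {
    spec <- cohort_spec(n_proteins = 150, n_samples = 250,
                        modules = list(list(size = 10, rho = r)),
                        missing_rate = 0, seed = 63)
    co <- generate_cohort(spec)
    cm <- correlation_matrix(co$matrix)
    ps <- generate_pair_set(co$truth, n_planted = 45, n_null = 0, seed = 64)
    pair_set_enrichment(cm, ps)$shift
  }, numeric(1L))
  expect_true(all(diff(shifts) > 0))
})

test_that("random_set_null is seed-reproducible and centered on the background", {
  spec <- cohort_spec(n_proteins = 200, n_samples = 150, modules = list(),
                      missing_rate = 0, seed = 65)
  cm <- correlation_matrix(generate_cohort(spec)$matrix)
  null1 <- random_set_null(cm, set_size = 5, n_draws = 200, seed = 66)
  null2 <- random_set_null(cm, set_size = 5, n_draws = 200, seed = 66)
  expect_identical(null1$values, null2$values)
  expect_lt(abs(null1$median - background_distribution(cm)$median), 0.05)

  one <- random_set_null(cm, set_size = 4, n_draws = 1, seed = 67)
  expect_identical(length(one$values), 1L)
  expect_error(random_set_null(cm, set_size = 500, n_draws = 1, seed = 1),
               "exceeds protein count")
})

test_that("independent cohorts show no median-of-medians shift", {
  spec <- cohort_spec(n_proteins = 200, n_samples = 150, modules = list(),
                      missing_rate = 0, seed = 68)
  co <- generate_cohort(spec)
  cm <- correlation_matrix(co$matrix)
  ann <- generate_annotation(co$truth, n_random_terms = 40,
                             random_term_size = 6, seed = 69)
  res <- all_term_medians(cm, ann)
  expect_lt(abs(res$medians$median - res$background$median), 0.05)
})
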