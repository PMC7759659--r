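test_that("subset masks map names to canonical bit positions", {
  nm <- cohort_schema()$features
  expect_equal(feature_subset(nm[1]), 1L)
  expect_equal(feature_subset(nm[c(1, 3)]), 5L)
  expect_equal(subset_names(5L), nm[c(1, 3)])
  expect_equal(subset_size(c(1L, 5L, 7L)), c(1L, 2L, 3L))
  expect_error(feature_subset("not_a_feature"), "unknown feature")
  expect_error(feature_subset(character(0)), "non-empty")
})

test_that("enumeration is exhaustive, ordered and matches the closed form", {
  # K = 3 canonical example
  expect_equal(enumerate_subsets(3), 1:7)
  # closed form verified by explicit enumeration for K <= 12
  for (k in 1:12) {
    masks <- enumerate_subsets(k)
    expect_equal(length(masks), 2^k - 1)
    expect_equal(length(masks), count_subsets(k))
    expect_false(anyDuplicated(masks) > 0)
    expect_true(all(diff(masks) > 0))
  }
  # exclusion removes the feature's bit entirely
  nm <- cohort_schema()$features
  masks <- enumerate_subsets(nm[1:5], exclude = nm[2])
  expect_equal(length(masks), 2^4 - 1)
  expect_true(all(bitwAnd(masks, feature_subset(nm[2])) == 0L))
  # size cap
  expect_equal(length(enumerate_subsets(10, max_size = 1)), 10)
  expect_equal(length(enumerate_subsets(10, max_size = 2)),
               count_subsets(10, max_size = 2))
  expect_error(enumerate_subsets(nm[1:2], exclude = nm[1:2]), "empty-domain")
})

make_toy_problem <- function(n = 90) {
  set.seed(10)
  y <- rep(0:1, c(n - 30, 30))
  X <- cbind(age = y * 3 + stats::rnorm(n),
             sex = stats::rnorm(n),
             eye = stats::rnorm(n))
  list(X = X, y = y)
}

test_that("serial and chunked searches are identical", {
  toy <- make_toy_problem()
  cfg <- search_config(features = c("age", "sex", "eye"), R = 5, seed = 11)
  serial <- search_subsets(toy$X, toy$y, cfg, chunks = 1)
  chunked <- search_subsets(toy$X, toy$y, cfg, chunks = 4)
  expect_identical(serial, chunked)
  expect_equal(nrow(serial), 7)
})

test_that("an informative feature outranks noise-only subsets", {
  toy <- make_toy_problem()
  cfg <- search_config(features = c("age", "sex", "eye"), R = 20, seed = 12)
  res <- search_subsets(toy$X, toy$y, cfg)
  best_with <- max(res$acc_mean[bitwAnd(res$mask, 1L) != 0L])
  best_without <- max(res$acc_mean[bitwAnd(res$mask, 1L) == 0L])
  expect_gt(best_with, best_without)
  top <- top_results(res, 1)
  expect_true(bitwAnd(top$mask, 1L) != 0L)
})

test_that("ranking sorts by ACC with size-then-mask tie-breaks", {
  res <- data.frame(
    mask = c(3L, 1L, 2L, 4L),
    size = c(2L, 1L, 1L, 1L),
    features = c("a+b", "a", "b", "c"),
    classifier = "x", R = 5L,
    acc_mean = c(86, 87, 86, 85), acc_sd = 1,
    spc_mean = 1, spc_sd = 1, tpr_mean = 1, tpr_sd = 1,
    failed = FALSE, seed = 1L)
  top <- top_results(res, 10)
  expect_equal(top$acc_mean, c(87, 86, 86, 85))
  # equal ACC 86: size-1 mask 2 before size-2 mask 3
  expect_equal(top$mask, c(1L, 2L, 3L, 4L))
  expect_equal(nrow(top_results(res, 2)), 2)
  res$failed <- TRUE
  expect_warning(empty <- top_results(res, 3), "no successful")
  expect_equal(nrow(empty), 0)
})

test_that("occurrence counts implement the strict threshold", {
  nm <- cohort_schema()$features
  mk <- function(feats) feature_subset(feats)
  res <- data.frame(
    mask = c(mk(c("age", "sex")), mk("sex"), mk(c("age", "eye"))),
    size = c(2L, 1L, 2L), features = "f", classifier = "x", R = 5L,
    acc_mean = c(80, 90, 50), acc_sd = 1, spc_mean = 1, spc_sd = 1,
    tpr_mean = 1, tpr_sd = 1, failed = FALSE, seed = 1L)
  occ <- occurrence_counts(res, 72)
  expect_equal(unname(occ[c("age", "sex", "eye")]), c(1L, 2L, 0L))
  expect_equal(attr(occ, "n_qualifying"), 2L)
  # strictness: a subset at exactly tau does not qualify
  expect_equal(attr(occurrence_counts(res, 80), "n_qualifying"), 1L)
  # unreachable threshold empties the qualifying set
  expect_true(all(occurrence_counts(res, 99) == 0L))
  # sum of counts equals the summed sizes of qualifying subsets
  expect_equal(sum(occurrence_counts(res, 72)), sum(res$size[res$acc_mean > 72]))
})

test_that("failed subsets are recorded, excluded from counts and ranking", {
  toy <- make_toy_problem()
  flaky <- classifier_spec(
    "custom",
    fit = function(X, y) {
      if (ncol(X) == 2) stop("boom")
      fit_discriminant(X, y, "diaglinear")
    },
    predict = function(m, X) predict(m, X))
  cfg <- search_config(features = c("age", "sex", "eye"), R = 4, seed = 13,
                       spec = flaky)
  res <- search_subsets(toy$X, toy$y, cfg)
  expect_equal(sum(res$failed), 3)            # the three 2-feature subsets
  expect_true(all(is.na(res$acc_mean[res$failed])))
  expect_false(any(top_results(res, 10)$failed))
  expect_equal(sum(occurrence_counts(res, 50)),
               sum(res$size[!res$failed & res$acc_mean > 50]))
})

test_that("indicator tables have the canonical layout", {
  toy <- make_toy_problem()
  cfg <- search_config(features = c("age", "sex", "eye"), R = 5, seed = 14)
  res <- search_subsets(toy$X, toy$y, cfg)
  tab <- format_indicator_table(res, 3)
  expect_equal(ncol(tab), 23)
  expect_equal(names(tab)[23], "acc")
  expect_true(all(unlist(tab[, 1:22]) %in% 0:1))
  expect_equal(unname(rowSums(tab[, 1:22])), top_results(res, 3)$size)
})

test_that("result ledgers round-trip through TSV", {
  toy <- make_toy_problem()
  cfg <- search_config(features = c("age", "sex"), R = 3, seed = 15)
  res <- search_subsets(toy$X, toy$y, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(res, path)
  back <- utils::read.delim(path)
  expect_equal(back$mask, res$mask)
  expect_equal(back$acc_mean, res$acc_mean, tolerance = 1e-6)
})
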