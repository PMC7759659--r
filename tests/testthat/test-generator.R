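test_that("truncated-normal sampler matches its closed/numeric oracle", {
  set.seed(1)
  # near-untruncated symmetric case
  x <- sample_truncated_normal(1e5, 0, 1, -10, 10)
  expect_lt(abs(mean(x)), 0.02)
  # degenerate interval
  y <- sample_truncated_normal(50, 0, 1, 0, 0.001)
  expect_true(all(y >= 0 & y <= 0.001))
  # asymmetric truncation: sample mean within 3 SE of the integration oracle
  for (par in list(c(70.2, 10.3, 10, 94), c(0.27, 0.19, 0, 0.95),
                   c(-1.36, 4.27, -30, 8.5))) {
    x <- sample_truncated_normal(1e5, par[1], par[2], par[3], par[4])
    om <- oracle_tn_mean(par[1], par[2], par[3], par[4])
    expect_lt(abs(mean(x) - om), 3 * stats::sd(x) / sqrt(length(x)))
    expect_true(all(x >= par[3] & x <= par[4]))
  }
  expect_error(sample_truncated_normal(10, 0, 1, 2, 2), "low < high")
  expect_error(sample_truncated_normal(10, 0, -1, 0, 1), "sd")
})

test_that("calibrated sampling locations reproduce the target means", {
  p <- default_generator_params()
  for (f in names(p$numeric)) {
    pf <- p$numeric[[f]]
    expect_lt(abs(oracle_tn_mean(pf$mu, pf$sd, pf$low, pf$high) - pf$mean),
              1e-6, label = f)
  }
})

test_that("null risk model gives ~50% prevalence", {
  p <- generator_params(risk_model = list(intercept = 0, surgeon = 0,
                                          al = 0, iol = 0),
                        calibrate = FALSE)
  co <- generate_cohort(p, seed = 3, n = 4000)
  expect_lt(abs(mean(co$complication) - 0.5), 3 * 0.5 / sqrt(4000))
})

test_that("complication increment shifts model time by exactly its value", {
  p <- default_generator_params()
  feats <- as.data.frame(generate_cohort(seed = 5, n = 50))
  tm <- utils::modifyList(p$time_model, list(complication = 15, scale = 1))
  t1 <- phacorisk:::time_terms(feats, rep(1L, 50), tm)
  t0 <- phacorisk:::time_terms(feats, rep(0L, 50), tm)
  expect_equal(t1 - t0, rep(15, 50))
})

test_that("generation is seed-deterministic and respects invariants", {
  a <- generate_cohort(seed = 11, n = 500)
  b <- generate_cohort(seed = 11, n = 500)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(seed = 12, n = 500)
  expect_false(identical(a$age, c2$age))

  sch <- cohort_schema()
  for (f in names(sch$numeric)) {
    rng <- sch$numeric[[f]]
    expect_true(all(a[[f]] >= rng[1] & a[[f]] <= rng[2]), label = f)
  }
  expect_true(all(a$surgery_time > 0))
  expect_true(all(a$complication %in% 0:1))
  expect_false(anyDuplicated(a$id) > 0)
  # derived identities
  expect_equal(a$spherical_equivalent, a$sphere + a$cylinder / 2)
  expect_equal(a$mean_k, (a$k1 + a$k2) / 2)
  expect_true(all(a$k2 >= a$k1))
})

test_that("categorical frequencies track the configured tables", {
  co <- generate_cohort(seed = 21, n = 5000)
  p <- default_generator_params()
  for (f in c("sex", "kind_of_surgeon", "cataract_type")) {
    fr <- p$categorical[[f]]
    for (lv in names(fr)) {
      se <- sqrt(fr[[lv]] * (1 - fr[[lv]]) / 5000)
      expect_lt(abs(mean(co[[f]] == lv) - fr[[lv]]), 4 * se + 1e-8,
                label = paste(f, lv))
    }
  }
})

test_that("resident stratum carries higher complication risk", {
  rates <- vapply(1:30, function(s) {
    co <- generate_cohort(seed = s, n = 1229)
    res <- co$kind_of_surgeon == "resident"
    c(mean(co$complication[res]), mean(co$complication[!res]))
  }, numeric(2))
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
})

test_that("optional AL-IOL copula induces the requested association", {
  p <- generator_params(al_iol_correlation = -0.5, calibrate = FALSE)
  co <- generate_cohort(p, seed = 31, n = 3000)
  expect_lt(stats::cor(co$axial_length, co$iol_power), -0.35)
  # marginals unaffected (inverse-CDF transform preserves them)
  om <- oracle_tn_mean(p$numeric$axial_length$mu, p$numeric$axial_length$sd,
                       p$numeric$axial_length$low, p$numeric$axial_length$high)
  expect_lt(abs(mean(co$axial_length) - om), 4 * 2.08 / sqrt(3000))
})

test_that("outcome model rejects unknown features", {
  p <- default_generator_params()
  expect_error(
    phacorisk:::risk_eta0(data.frame(axial_length = 1), p$risk_model),
    "unknown feature")
  expect_error(generate_cohort(p, seed = 1, n = 0), "parameter error")
  expect_error(generate_cohort(p, n = 10), "seed")
})
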