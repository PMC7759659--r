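test_that("fitting recovers sample means, priors and degenerate variances", {
  X <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c(0, 0, 1, 1)
  m <- fit_discriminant(X, y, "diaglinear")
  expect_equal(unname(m$means[, 1]), c(-1, 1))
  expect_equal(unname(m$priors), c(0.5, 0.5))
  # zero pooled variance is replaced by the epsilon floor
  expect_gt(m$variances[[1]], 0)
  # symmetric tie at x = 0 breaks to the lower class
  expect_equal(predict(m, matrix(0)), 0)

  expect_error(fit_discriminant(X, rep(1, 4), "linear"), "two classes")
  expect_error(fit_discriminant(X, c(0, 1, 1, 1), "linear"), "at least 2")
})

test_that("all five variants match the brute-force density oracle", {
  for (seed in 1:100) {
    inst <- make_gaussian_instance(seed, n = 40, p = 1 + seed %% 3)
    for (v in c("linear", "diaglinear", "quadratic", "diagquadratic",
                "mahalanobis")) {
      m <- fit_discriminant(inst$X, inst$y, v, epsilon = 1e-8)
      got <- predict(m, inst$Xte)
      want <- oracle_discriminant_predict(inst$X, inst$y, inst$Xte, v, 1e-8)
      expect_equal(got, want, label = paste("seed", seed, v))
    }
  }
})

test_that("prediction at a class mean picks that class; scores are finite", {
  inst <- make_gaussian_instance(7, n = 60, p = 2, delta = 6)
  for (v in c("linear", "diaglinear", "quadratic", "diagquadratic",
              "mahalanobis")) {
    m <- fit_discriminant(inst$X, inst$y, v)
    expect_equal(predict(m, m$means[2, , drop = FALSE]), 1, label = v)
    expect_true(all(is.finite(predict(m, inst$Xte, type = "score"))))
  }
  m <- fit_discriminant(inst$X, inst$y, "linear")
  expect_error(predict(m, inst$Xte[, 1, drop = FALSE]), "shape error")
})

test_that("linear and quadratic agree when class covariances are identical", {
  set.seed(3)
  cloud <- matrix(stats::rnorm(80), ncol = 2)
  X <- rbind(cloud, sweep(cloud, 2, c(2.5, -1), `+`))
  y <- rep(0:1, each = 40)
  grid <- as.matrix(expand.grid(seq(-3, 6, length = 12),
                                seq(-4, 3, length = 12)))
  ml <- fit_discriminant(X, y, "linear", epsilon = 1e-10)
  mq <- fit_discriminant(X, y, "quadratic", epsilon = 1e-10)
  expect_equal(predict(ml, grid), predict(mq, grid))
})

test_that("diagonal and full variants coincide in one dimension", {
  set.seed(4)
  X <- matrix(c(stats::rnorm(30, 0, 1), stats::rnorm(25, 2, 1.7)), ncol = 1)
  y <- c(rep(0, 30), rep(1, 25))
  xte <- matrix(seq(-3, 6, length = 50), ncol = 1)
  expect_equal(
    predict(fit_discriminant(X, y, "diaglinear"), xte),
    predict(fit_discriminant(X, y, "linear"), xte))
  expect_equal(
    predict(fit_discriminant(X, y, "diagquadratic"), xte),
    predict(fit_discriminant(X, y, "quadratic"), xte))
})

test_that("mahalanobis decisions are invariant under affine maps", {
  inst <- make_gaussian_instance(12, n = 80, p = 3, delta = 2)
  A <- matrix(c(2, 0.5, 0, -1, 1.5, 0.3, 0.2, 0, 1), 3, 3)
  b <- c(5, -2, 100)
  tf <- function(M) sweep(M %*% t(A), 2, b, `+`)
  m1 <- fit_discriminant(inst$X, inst$y, "mahalanobis", epsilon = 1e-10)
  m2 <- fit_discriminant(tf(inst$X), inst$y, "mahalanobis", epsilon = 1e-10)
  expect_equal(predict(m1, inst$Xte), predict(m2, tf(inst$Xte)))
})

test_that("posteriors are calibrated softmax scores", {
  X <- matrix(c(stats::rnorm(40, -1), stats::rnorm(40, 1)), ncol = 1)
  y <- rep(0:1, each = 40)
  # force exact symmetry: mirror class 0 into class 1
  X[41:80, 1] <- -X[1:40, 1]
  m <- fit_discriminant(X, y, "linear")
  mid <- matrix((m$means[1, ] + m$means[2, ]) / 2, 1)
  expect_equal(unname(posterior(m, mid)[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  pr <- posterior(m, matrix(seq(-3, 3, length = 21), ncol = 1))
  expect_equal(rowSums(pr), rep(1, 21), tolerance = 1e-12)
  far <- matrix(m$means[2, ] + 10 * sqrt(m$cov[[1]][1, 1]), 1)
  expect_gt(posterior(m, far)[1, 2], 0.999)
  mm <- fit_discriminant(X, y, "mahalanobis")
  expect_error(posterior(mm, mid), "unsupported")
})

test_that("models serialize to JSON and back with identical predictions", {
  inst <- make_gaussian_instance(5, n = 50, p = 2)
  for (v in c("diaglinear", "quadratic", "mahalanobis")) {
    m <- fit_discriminant(inst$X, inst$y, v)
    path <- withr::local_tempfile(fileext = ".json")
    discriminant_to_json(m, path)
    m2 <- discriminant_from_json(path)
    expect_equal(predict(m2, inst$Xte), predict(m, inst$Xte), label = v)
    expect_equal(m2$variant, v)
  }
})

test_that("classifier specs wrap fit/predict uniformly", {
  inst <- make_gaussian_instance(6, n = 60, p = 2, delta = 4)
  spec <- classifier_spec("discriminant", "quadratic")
  model <- spec$fit(inst$X, inst$y)
  expect_s3_class(model, "discriminant_model")
  # gaussian naive Bayes is exactly the diagquadratic rule
  nb <- classifier_spec("naive_bayes")
  expect_equal(nb$predict(nb$fit(inst$X, inst$y), inst$Xte),
               predict(fit_discriminant(inst$X, inst$y, "diagquadratic"),
                       inst$Xte))
  # custom family requires both functions
  expect_error(classifier_spec("custom"), "requires fit")
  cs <- classifier_spec("custom",
                        fit = function(X, y) stats::glm.fit(cbind(1, X), y,
                          family = stats::binomial()),
                        predict = function(m, X)
                          as.integer(drop(cbind(1, X) %*% m$coefficients) > 0))
  expect_type(cs$predict(cs$fit(inst$X, inst$y), inst$Xte), "integer")
})
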