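# Independent oracles used by the unit and acceptance tests. These must not
# share code paths with the package: densities are evaluated with explicit
# solve()/det() formulas, counts with plain loops, moments with numeric
# integration.

# truncated-normal mean by numeric integration (independent of the
# package's closed form)
oracle_tn_mean <- function(mean, sd, low, high) {
  z <- stats::pnorm(high, mean, sd) - stats::pnorm(low, mean, sd)
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / z,
                   low, high, rel.tol = 1e-10)$value
}

# multivariate normal log density via explicit inverse and determinant
oracle_mvn_logdens <- function(x, mu, S) {
  p <- length(mu)
  d <- x - mu
  -0.5 * (p * log(2 * pi) + log(det(S)) +
            drop(t(d) %*% solve(S) %*% d))
}

# brute-force discriminant predictions, one observation at a time
oracle_discriminant_predict <- function(Xtr, y, Xte, variant, eps) {
  classes <- sort(unique(y))
  mus <- lapply(classes, function(c) colMeans(Xtr[y == c, , drop = FALSE]))
  ns <- vapply(classes, function(c) sum(y == c), numeric(1))
  priors <- ns / length(y)
  p <- ncol(Xtr)
  covs <- lapply(seq_along(classes), function(k) {
    Xi <- Xtr[y == classes[k], , drop = FALSE]
    d <- sweep(Xi, 2, mus[[k]])
    t(d) %*% d
  })
  pooled <- (covs[[1]] + covs[[2]]) / (length(y) - 2)
  Sig <- switch(variant,
    linear = rep(list(pooled + diag(eps, p)), 2),
    diaglinear = rep(list(diag(diag(pooled), p) + diag(eps, p)), 2),
    quadratic = ,
    mahalanobis = lapply(1:2, function(k)
      covs[[k]] / (ns[k] - 1) + diag(eps, p)),
    diagquadratic = lapply(1:2, function(k)
      diag(diag(covs[[k]] / (ns[k] - 1)), p) + diag(eps, p))
  )
  apply(Xte, 1, function(x) {
    sc <- vapply(1:2, function(k) {
      if (variant == "mahalanobis") {
        d <- x - mus[[k]]
        -drop(t(d) %*% solve(Sig[[k]]) %*% d)
      } else {
        log(priors[k]) + oracle_mvn_logdens(x, mus[[k]], Sig[[k]])
      }
    }, numeric(1))
    # lower class index on ties
    classes[which(sc == max(sc))[1]]
  })
}

# plain-loop confusion counts
oracle_metrics <- function(y_true, y_pred, positive = 1) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == positive && y_pred[i] == positive) tp <- tp + 1
    else if (y_true[i] != positive && y_pred[i] != positive) tn <- tn + 1
    else if (y_true[i] != positive && y_pred[i] == positive) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       acc = 100 * (tp + tn) / length(y_true),
       tpr = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       spc = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

# random small two-class Gaussian instance
make_gaussian_instance <- function(seed, n = 40, p = 2, delta = 1.5) {
  set.seed(seed)
  n1 <- sample(5:(n - 5), 1)
  mu0 <- stats::rnorm(p)
  mu1 <- mu0 + stats::runif(p, -delta, delta)
  sd0 <- stats::runif(p, 0.5, 2)
  sd1 <- stats::runif(p, 0.5, 2)
  X <- rbind(
    sweep(sweep(matrix(stats::rnorm((n - n1) * p), ncol = p), 2, sd0, `*`),
          2, mu0, `+`),
    sweep(sweep(matrix(stats::rnorm(n1 * p), ncol = p), 2, sd1, `*`),
          2, mu1, `+`))
  y <- c(rep(0, n - n1), rep(1, n1))
  Xte <- rbind(
    sweep(sweep(matrix(stats::rnorm(8 * p), ncol = p), 2, sd0, `*`),
          2, mu0, `+`),
    sweep(sweep(matrix(stats::rnorm(7 * p), ncol = p), 2, sd1, `*`),
          2, mu1, `+`))
  list(X = X, y = y, Xte = Xte)
}

# planted-signal generator: monotone (range-minimum-centred) risk effects on
# surgeon / axial length / IOL power so a linear-boundary classifier can see
# them; prevalence recalibrated to the study's 73/1229
planted_generator_params <- function() {
  generator_params(risk_model = list(surgeon = 3.0,
                                     al = 0.5, al_center = 17,
                                     iol = 0.2, iol_center = -7))
}

# a small, valid cohort data.frame built by code (for I/O tests)
tiny_cohort_df <- function(n = 5) {
  as.data.frame(generate_cohort(seed = 99, n = n))
}
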