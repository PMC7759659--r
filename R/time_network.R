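# Surgery-time prediction with a single-hidden-layer backpropagation
# network: 21 input neurons (the canonical features minus surgery time),
# 10 sigmoid hidden neurons, one linear output. Trained by full-batch
# gradient descent with momentum on the mean squared error of the
# standardized target. Feature configurations are expressed as bitmasks;
# non-member inputs are zeroed, so the architecture (and the input layer
# width) is the same for every configuration.

#' Network / training specification
#'
#' Two full-batch trainers are available. `"lm"` (default) is damped
#' Gauss-Newton (Levenberg-Marquardt), the standard trainer for small
#' feedforward regression networks: fast, deterministic and far less
#' sensitive to the weight initialisation than first-order descent.
#' `"gd"` is plain backpropagation gradient descent with classical
#' momentum, kept as the reference first-order option.
#'
#' @param hidden hidden-layer width (default 10).
#' @param epochs full-batch iterations: LM steps, or gradient steps.
#' @param algorithm `"lm"` or `"gd"`.
#' @param learning_rate step size of the `"gd"` trainer (standardized
#'   problem).
#' @param momentum classical momentum coefficient of the `"gd"` trainer.
#' @param activation hidden activation (`"sigmoid"` or `"tanh"`).
#' @param standardize standardize inputs to zero mean / unit SD (the target
#'   is always standardized internally and predictions mapped back).
#' @return A `network_spec`.
#' @export
network_spec <- function(hidden = 10, epochs = NULL,
                         algorithm = c("lm", "gd"),
                         learning_rate = 0.05, momentum = 0.9,
                         activation = c("sigmoid", "tanh"),
                         standardize = TRUE) {
  activation <- match.arg(activation)
  algorithm <- match.arg(algorithm)
  if (is.null(epochs)) epochs <- if (algorithm == "lm") 200 else 2000
  if (!is_count(hidden)) stop("hidden size must be >= 1")
  if (!is_count(epochs)) stop("epochs must be >= 1")
  structure(list(hidden = hidden, epochs = epochs, algorithm = algorithm,
                 learning_rate = learning_rate, momentum = momentum,
                 activation = activation, standardize = standardize),
            class = "network_spec")
}

#' Train the surgery-time network
#'
#' @param X numeric matrix (n x p) of encoded inputs.
#' @param t target times in minutes (`t > 0`).
#' @param spec a [network_spec()].
#' @param seed weight-initialisation seed (training is deterministic given
#'   the seed).
#' @return A `time_network`: weights, input/target scalings, the loss
#'   trajectory and the spec.
#' @export
fit_time_network <- function(X, t, spec = network_spec(), seed = 1L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  t <- as.numeric(t)
  n <- nrow(X); p <- ncol(X); h <- spec$hidden
  if (length(t) != n) stop("shape error: length(t) != nrow(X)")
  if (anyNA(X) || anyNA(t)) stop("missing values are not allowed")
  if (any(t <= 0)) stop("target times must be positive")

  if (spec$standardize) {
    xc <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  } else {
    xc <- rep(0, p); xs <- rep(1, p)
  }
  Z <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  tc <- mean(t); ts <- stats::sd(t); if (ts == 0) ts <- 1
  tz <- (t - tc) / ts

  act <- switch(spec$activation,
                sigmoid = function(z) 1 / (1 + exp(-z)),
                tanh = tanh)
  dact <- switch(spec$activation,
                 sigmoid = function(a) a * (1 - a),
                 tanh = function(a) 1 - a^2)

  init <- with_seed(seed, {
    r1 <- sqrt(6 / (p + h)); r2 <- sqrt(6 / (h + 1))
    list(W1 = matrix(stats::runif(p * h, -r1, r1), p, h),
         W2 = matrix(stats::runif(h, -r2, r2), h, 1))
  })
  W1 <- init$W1; b1 <- rep(0, h); W2 <- init$W2; b2 <- 0

  forward <- function() {
    A <- act(sweep(Z %*% W1, 2, b1, `+`))
    list(A = A, yhat = drop(A %*% W2) + b2)
  }

  if (spec$algorithm == "gd") {
    vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- 0
    lr <- spec$learning_rate; mom <- spec$momentum
    loss <- numeric(spec$epochs)
    for (e in seq_len(spec$epochs)) {
      fw <- forward()
      err <- fw$yhat - tz
      loss[e] <- mean(err^2)
      if (!is.finite(loss[e]))
        stop("training error: non-finite loss at epoch ", e)
      g <- 2 * err / n
      dW2 <- crossprod(fw$A, g)
      db2 <- sum(g)
      dA <- outer(g, drop(W2)) * dact(fw$A)   # n x h
      dW1 <- crossprod(Z, dA)
      db1 <- colSums(dA)
      vW2 <- mom * vW2 - lr * dW2; W2 <- W2 + vW2
      vb2 <- mom * vb2 - lr * db2; b2 <- b2 + vb2
      vW1 <- mom * vW1 - lr * dW1; W1 <- W1 + vW1
      vb1 <- mom * vb1 - lr * db1; b1 <- b1 + vb1
    }
    if (loss[spec$epochs] > loss[1])
      stop("training error: loss diverged (final ", format(loss[spec$epochs]),
           " > initial ", format(loss[1]), ")")
  } else {
    # Levenberg-Marquardt: residual r_i = yhat_i - tz_i, Jacobian of yhat
    # w.r.t. theta = (vec(W1), b1, W2, b2); solve (J'J + lambda I) d = -J'r.
    nw <- p * h + h + h + 1L
    unpack <- function(th) {
      list(W1 = matrix(th[seq_len(p * h)], p, h),
           b1 = th[p * h + seq_len(h)],
           W2 = matrix(th[p * h + h + seq_len(h)], h, 1),
           b2 = th[nw])
    }
    th <- c(as.numeric(W1), b1, as.numeric(W2), b2)
    jac <- function(A, Zq) {
      # A: n x h activations; returns n x nw Jacobian
      D <- dact(A)                           # s'(z), n x h
      J <- matrix(0, n, nw)
      for (j in seq_len(h)) {
        w2j <- drop(W2)[j]
        J[, (j - 1L) * p + seq_len(p)] <- (w2j * D[, j]) * Zq
      }
      J[, p * h + seq_len(h)] <- sweep(D, 2, drop(W2), `*`)
      J[, p * h + h + seq_len(h)] <- A
      J[, nw] <- 1
      J
    }
    lambda <- 1e-2
    fw <- forward()
    r <- fw$yhat - tz
    cost <- sum(r^2)
    loss <- numeric(spec$epochs)
    for (e in seq_len(spec$epochs)) {
      loss[e] <- cost / n
      if (!is.finite(cost))
        stop("training error: non-finite loss at epoch ", e)
      J <- jac(fw$A, Z)
      g <- crossprod(J, r)
      H <- crossprod(J)
      accepted <- FALSE
      for (k in 1:30) {
        step <- tryCatch(
          -solve(H + diag(lambda, nw), g),
          error = function(err) NULL)
        if (!is.null(step)) {
          th_new <- th + drop(step)
          cand <- unpack(th_new)
          W1n <- cand$W1; b1n <- cand$b1; W2n <- cand$W2; b2n <- cand$b2
          An <- act(sweep(Z %*% W1n, 2, b1n, `+`))
          rn <- drop(An %*% W2n) + b2n - tz
          costn <- sum(rn^2)
          if (is.finite(costn) && costn < cost) {
            th <- th_new; W1 <- W1n; b1 <- b1n; W2 <- W2n; b2 <- b2n
            fw <- list(A = An, yhat = rn + tz)
            r <- rn; cost <- costn
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e12) break
      }
      if (!accepted) { loss <- loss[seq_len(e)]; break }  # converged
      if (sqrt(sum(g^2)) < 1e-10) { loss <- loss[seq_len(e)]; break }
    }
  }

  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 x_center = xc, x_scale = xs, t_center = tc, t_scale = ts,
                 activation = spec$activation, loss = loss, spec = spec,
                 seed = seed, features = colnames(X)),
            class = "time_network")
}

#' Predict surgery times
#'
#' @param object a `time_network`.
#' @param newdata matrix with the training columns.
#' @param ... unused.
#' @return Predicted times in minutes.
#' @export
predict.time_network <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_center))
    stop("shape error: expected ", length(object$x_center), " columns")
  Z <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  act <- switch(object$activation,
                sigmoid = function(z) 1 / (1 + exp(-z)),
                tanh = tanh)
  A <- act(sweep(Z %*% object$W1, 2, object$b1, `+`))
  yz <- drop(A %*% object$W2) + object$b2
  yz * object$t_scale + object$t_center
}

#' Maximum absolute prediction error
#'
#' @param predicted,actual equal-length numeric vectors (minutes).
#' @return `max |predicted - actual|` in minutes.
#' @export
max_abs_error <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("shape error: predicted and actual differ in length")
  if (length(predicted) == 0) stop("empty vectors")
  max(abs(predicted - actual))
}

# Zero the non-member input columns of a configuration mask. X columns must
# be canonical feature names; features of the mask absent from X are an
# error.
mask_inputs <- function(X, mask) {
  members <- subset_names(mask)
  missing_f <- setdiff(members, colnames(X))
  if (length(missing_f) > 0)
    stop("configuration references inputs absent from X: ",
         paste(missing_f, collapse = ", "))
  Xm <- X
  Xm[, !(colnames(X) %in% members)] <- 0
  Xm
}

#' Scan feature configurations for surgery-time prediction
#'
#' For each configuration: zero the non-member inputs, train the network on
#' a fixed (per scan) 2/3 train / 1/3 test split, and record the maximum
#' absolute test error and test MSE. Training failures are recorded per
#' configuration without aborting the scan.
#'
#' @param X numeric input matrix with canonical feature columns (surgery
#'   time must not be among them).
#' @param t target surgery times (minutes).
#' @param configurations vector of configuration bitmasks (or list of
#'   name vectors).
#' @param spec a [network_spec()].
#' @param split_fraction held-out fraction (default 1/3).
#' @param seed master seed: drives the split and each configuration's
#'   weight initialisation (derived per mask, order-free).
#' @param strata optional vector (e.g. the complication labels) to
#'   stratify the split on.
#' @return A `time_scan` data.frame: `mask`, `size`, `features`,
#'   `max_abs_error`, `mse`, `rmse`, `failed`, `seed`; the best (smallest
#'   max-abs-error) configuration is in attribute `"best"`.
#' @export
scan_configurations <- function(X, t, configurations, spec = network_spec(),
                                split_fraction = 1/3, seed = 1L,
                                strata = NULL) {
  if (length(configurations) == 0) stop("configurations must be non-empty")
  if ("surgery_time" %in% colnames(X))
    stop("surgery time is the target and cannot be an input")
  masks <- vapply(configurations, function(s) as_subset_mask(s), numeric(1))
  n <- nrow(X)
  test <- with_seed(derive_seed(seed, 0, 0), {
    if (is.null(strata)) sample(n, round(n * split_fraction))
    else stratified_split(seq_len(n), strata, split_fraction)$test
  })
  train <- setdiff(seq_len(n), test)

  rows <- lapply(masks, function(m) {
    res <- tryCatch({
      Xm <- mask_inputs(X, m)
      net <- fit_time_network(Xm[train, , drop = FALSE], t[train], spec,
                              seed = derive_seed(seed, m, 1))
      pred <- predict(net, Xm[test, , drop = FALSE])
      mse <- mean((pred - t[test])^2)
      c(max_abs_error = max_abs_error(pred, t[test]), mse = mse,
        rmse = sqrt(mse))
    }, error = function(e) e)
    if (inherits(res, "error"))
      data.frame(mask = m, size = subset_size(m),
                 features = paste(subset_names(m), collapse = "+"),
                 max_abs_error = NA_real_, mse = NA_real_, rmse = NA_real_,
                 failed = TRUE, seed = seed, stringsAsFactors = FALSE)
    else
      data.frame(mask = m, size = subset_size(m),
                 features = paste(subset_names(m), collapse = "+"),
                 max_abs_error = res[["max_abs_error"]], mse = res[["mse"]],
                 rmse = res[["rmse"]], failed = FALSE, seed = seed,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- which(!out$failed)
  attr(out, "best") <- if (length(ok) > 0)
    out[ok[which.min(out$max_abs_error[ok])], , drop = FALSE] else NULL
  class(out) <- c("time_scan", "data.frame")
  out
}

#' Compare predicted and actual surgery times
#'
#' Normality of the paired differences is screened with a Kolmogorov-
#' Smirnov test against a normal with the sample moments (a flag only; the
#' parameters are estimated, so the p-value is approximate). The paired
#' comparison is a Student t test on the differences; MSE is their mean
#' square.
#'
#' @param predicted,actual equal-length vectors (minutes), `n >= 3`.
#' @return A list: `n`, `mse`, `mean_diff`, `t`, `p`, `ks_p`,
#'   `normal` (KS flag at 0.05), `degenerate` (zero-variance differences:
#'   `t` and `p` are `NA`), plus means/SDs of both vectors.
#' @export
compare_times <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("shape error: predicted and actual differ in length")
  n <- length(predicted)
  if (n < 3) stop("need at least 3 paired observations")
  d <- predicted - actual
  mse <- mean(d^2)
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
    ks <- list(p.value = NA_real_)
  } else {
    tt <- stats::t.test(predicted, actual, paired = TRUE)
    ks <- suppressWarnings(
      stats::ks.test(d, "pnorm", mean(d), stats::sd(d)))
  }
  list(n = n, mse = mse, mean_diff = mean(d),
       t = unname(tt$statistic), p = tt$p.value,
       ks_p = ks$p.value, normal = if (degenerate) NA else ks$p.value > 0.05,
       degenerate = degenerate,
       predicted_mean = mean(predicted), predicted_sd = stats::sd(predicted),
       actual_mean = mean(actual), actual_sd = stats::sd(actual))
}
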