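# Gaussian discriminant classifiers, implemented from their density
# formulas. Five variants differing in the covariance structure:
#
#   linear        pooled full covariance          (shared across classes)
#   diaglinear    pooled per-feature variances    (shared, diagonal)
#   quadratic     per-class full covariance
#   diagquadratic per-class per-feature variances
#   mahalanobis   per-class full covariance, distance-only rule
#
# The four density-based variants assign argmax_c of
#   log pi_c - 1/2 log|Sigma_c| - 1/2 (x-mu_c)' Sigma_c^{-1} (x-mu_c);
# the mahalanobis variant assigns argmin_c of the squared Mahalanobis
# distance with per-class covariance and no prior or determinant terms.
# Ties break deterministically to the lower class index.

DISCRIMINANT_VARIANTS <- c("linear", "diaglinear", "quadratic",
                           "diagquadratic", "mahalanobis")

#' Fit a Gaussian discriminant model
#'
#' @param X numeric matrix (n x p) of encoded features.
#' @param y binary labels (two distinct values; sorted order defines class
#'   indices, lower value = class index 1).
#' @param variant one of `"linear"`, `"diaglinear"`, `"quadratic"`,
#'   `"diagquadratic"`, `"mahalanobis"`.
#' @param epsilon ridge added to every stored variance / covariance
#'   diagonal. Default `1e-6` times the mean pooled per-feature variance
#'   (floored at `1e-12`); escalated tenfold, with a message, if a full
#'   covariance is still not positive definite.
#' @return A `discriminant_model`: class means, covariance structure per
#'   variant, empirical class priors, the regularisation used, and the
#'   feature names it was fitted on.
#' @export
fit_discriminant <- function(X, y, variant = DISCRIMINANT_VARIANTS,
                             epsilon = NULL) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("shape error: length(y) != nrow(X)")
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("fit error: need exactly two classes in y, found ", length(classes))
  idx <- lapply(classes, function(c) which(y == c))
  nc <- lengths(idx)
  if (any(nc < 2L))
    stop("fit error: need at least 2 records per class for variance estimation")

  means <- lapply(idx, function(i) colMeans(X[i, , drop = FALSE]))
  centred <- lapply(seq_along(classes), function(k) {
    sweep(X[idx[[k]], , drop = FALSE], 2, means[[k]])
  })
  scatter <- lapply(centred, crossprod)           # Sc = sum (x-mu)(x-mu)'
  pooled_cov <- (scatter[[1]] + scatter[[2]]) / (n - 2)
  pooled_var <- diag(pooled_cov)

  if (is.null(epsilon)) epsilon <- max(1e-6 * mean(pooled_var), 1e-12)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")

  # chol with escalating ridge for degenerate covariances
  safe_chol <- function(S, eps) {
    for (k in 0:20) {
      R <- tryCatch(chol(S + diag(eps * 10^k, ncol(S))), error = function(e) NULL)
      if (!is.null(R)) {
        if (k > 0) message("covariance regularisation escalated to ",
                           format(eps * 10^k))
        return(list(R = R, eps = eps * 10^k))
      }
    }
    stop("fit error: covariance not positive definite even after regularisation")
  }

  model <- list(variant = variant, classes = classes,
                means = do.call(rbind, means), priors = nc / n,
                epsilon = epsilon, n = n, p = p,
                features = colnames(X))
  if (variant == "linear") {
    ch <- safe_chol(pooled_cov, epsilon)
    model$chol <- list(ch$R)
    model$cov <- list(pooled_cov + diag(ch$eps, p))
    model$shared_cov <- TRUE
  } else if (variant == "diaglinear") {
    model$variances <- list(pooled_var + epsilon)
    model$shared_cov <- TRUE
  } else if (variant %in% c("quadratic", "mahalanobis")) {
    covs <- lapply(seq_along(classes), function(k) scatter[[k]] / (nc[k] - 1))
    chs <- lapply(covs, safe_chol, eps = epsilon)
    model$chol <- lapply(chs, `[[`, "R")
    model$cov <- lapply(seq_along(covs), function(k)
      covs[[k]] + diag(chs[[k]]$eps, p))
    model$shared_cov <- FALSE
  } else { # diagquadratic
    model$variances <- lapply(seq_along(classes), function(k)
      diag(scatter[[k]]) / (nc[k] - 1) + epsilon)
    model$shared_cov <- FALSE
  }
  class(model) <- "discriminant_model"
  model
}

# Per-class discriminant scores for a matrix of observations.
# Density-based variants: joint log density log pi_c + log N(x; mu_c, Sigma_c)
# (the -p/2 log 2pi constant is shared and omitted).
# Mahalanobis variant: negative squared distance.
discriminant_scores <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$p)
    stop("shape error: model was fitted on ", model$p, " features, got ",
         ncol(X))
  n <- nrow(X)
  scores <- matrix(NA_real_, n, 2L)
  for (k in 1:2) {
    dx <- sweep(X, 2, model$means[k, ])
    if (model$variant %in% c("diaglinear", "diagquadratic")) {
      v <- model$variances[[min(k, length(model$variances))]]
      maha <- rowSums(sweep(dx^2, 2, v, `/`))
      logdet <- sum(log(v))
    } else {
      R <- model$chol[[min(k, length(model$chol))]]
      z <- backsolve(R, t(dx), transpose = TRUE)    # R'z = dx'
      maha <- colSums(z^2)
      logdet <- 2 * sum(log(diag(R)))
    }
    scores[, k] <- if (model$variant == "mahalanobis") {
      -maha
    } else {
      log(model$priors[k]) - 0.5 * logdet - 0.5 * maha
    }
  }
  colnames(scores) <- as.character(model$classes)
  scores
}

#' Predict classes from a discriminant model
#'
#' @param object a `discriminant_model`.
#' @param newdata numeric matrix with the model's feature columns.
#' @param type `"class"` for hard labels, `"score"` for the per-class
#'   discriminant scores.
#' @param ... unused.
#' @return Labels on the scale of the training `y`, or a score matrix.
#' @export
predict.discriminant_model <- function(object, newdata,
                                       type = c("class", "score"), ...) {
  type <- match.arg(type)
  scores <- discriminant_scores(object, newdata)
  if (type == "score") return(scores)
  # ties.method = "first" implements the lower-class-index tie break
  object$classes[max.col(scores, ties.method = "first")]
}

#' Posterior class probabilities
#'
#' Softmax of the per-class joint log scores. The mahalanobis variant is a
#' pure distance rule with no calibrated posterior and is rejected.
#'
#' @param model a `discriminant_model`.
#' @param X numeric matrix of observations.
#' @return n x 2 matrix of probabilities summing to 1 per row.
#' @export
posterior <- function(model, X) {
  stopifnot(inherits(model, "discriminant_model"))
  if (model$variant == "mahalanobis")
    stop("unsupported operation: the mahalanobis variant has no posterior")
  s <- discriminant_scores(model, X)
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Gaussian discriminant model (", x$variant, ")\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = " / "),
      " priors:", paste(round(x$priors, 3), collapse = " / "), "\n")
  cat("  features (", x$p, "): ",
      paste(x$features %||% paste0("V", seq_len(x$p)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a discriminant model to JSON
#'
#' @param model a `discriminant_model`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
discriminant_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "discriminant_model"))
  doc <- list(
    variant = model$variant,
    classes = model$classes,
    means = model$means,
    priors = as.numeric(model$priors),
    epsilon = model$epsilon,
    features = model$features,
    covariances = if (!is.null(model$cov)) model$cov else NULL,
    variances = if (!is.null(model$variances)) model$variances else NULL
  )
  json <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Deserialize a discriminant model from JSON
#'
#' @param path file path or JSON string produced by [discriminant_to_json()].
#' @return A `discriminant_model`.
#' @export
discriminant_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  m <- list(variant = doc$variant, classes = doc$classes,
            means = as.matrix(doc$means), priors = as.numeric(doc$priors),
            epsilon = doc$epsilon, features = doc$features,
            p = ncol(as.matrix(doc$means)), n = NA_integer_,
            shared_cov = doc$variant %in% c("linear", "diaglinear"))
  if (!is.null(doc$covariances)) {
    covs <- doc$covariances
    if (is.array(covs) && length(dim(covs)) == 3)
      covs <- lapply(seq_len(dim(covs)[1]), function(i) covs[i, , ])
    if (is.matrix(covs)) covs <- list(covs)
    m$cov <- lapply(covs, as.matrix)
    m$chol <- lapply(m$cov, chol)
  }
  if (!is.null(doc$variances)) {
    v <- doc$variances
    if (is.matrix(v)) v <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    if (is.numeric(v)) v <- list(v)
    m$variances <- v
  }
  class(m) <- "discriminant_model"
  m
}

#' Classifier specification (pluggable binary-classifier interface)
#'
#' The feature-subset search and the balanced evaluator accept any binary
#' classifier exposing `fit(X, y) -> model` and `predict(model, X) ->
#' labels`. The discriminant family is implemented natively; a Gaussian
#' naive Bayes spec maps onto the diagquadratic variant (the two rules are
#' identical: per-class means, per-class per-feature variances, empirical
#' priors). Other families from the usual bake-off (neural network,
#' decision tree, support vector machine) are accepted as `family =
#' "custom"` with user-supplied `fit`/`predict`, since no backend for them
#' ships with the package's declared dependencies.
#'
#' @param family `"discriminant"`, `"naive_bayes"` or `"custom"`.
#' @param variant discriminant variant (for `family = "discriminant"`).
#' @param epsilon optional ridge passed to [fit_discriminant()].
#' @param fit,predict functions for `family = "custom"`.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("discriminant", "naive_bayes", "custom"),
                            variant = "diaglinear", epsilon = NULL,
                            fit = NULL, predict = NULL) {
  family <- match.arg(family)
  if (family == "discriminant") {
    variant <- match.arg(variant, DISCRIMINANT_VARIANTS)
    spec <- list(
      family = family, label = paste0("discriminant:", variant),
      fit = function(X, y) fit_discriminant(X, y, variant, epsilon),
      predict = function(model, X) stats::predict(model, X))
  } else if (family == "naive_bayes") {
    spec <- list(
      family = family, label = "naive_bayes(gaussian)",
      fit = function(X, y) fit_discriminant(X, y, "diagquadratic", epsilon),
      predict = function(model, X) stats::predict(model, X))
  } else {
    if (!is.function(fit) || !is.function(predict))
      stop("family 'custom' requires fit(X, y) and predict(model, X) functions")
    spec <- list(family = family, label = "custom", fit = fit, predict = predict)
  }
  structure(spec, class = "classifier_spec")
}
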