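# Balanced-undersampling, repeated-randomization evaluation.
#
# The complication class is a small minority (73 of 1,229), so each
# randomization draws a balanced working set: every minority record plus an
# equally sized uniform sample (without replacement) of the majority. The
# working set is then split, stratified by class, into training and test
# portions, a classifier is fitted, and accuracy / specificity /
# sensitivity are recorded on the held-out portion. Means and SDs over R
# randomizations summarise one (feature subset, classifier) pair.

#' Draw one balanced undersample
#'
#' Returns the indices of all minority-class records plus an equal number
#' of majority-class records drawn uniformly without replacement, using the
#' current RNG state.
#'
#' @param labels binary label vector.
#' @param positive value of the minority/positive class (default `1`).
#' @return Integer vector of `2 m` record indices, `m` per class.
#' @export
balanced_sample <- function(labels, positive = 1) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  if (length(pos) > length(neg)) { tmp <- pos; pos <- neg; neg <- tmp }
  m <- length(pos)
  if (m < 2) stop("evaluation error: minority class has fewer than 2 records")
  if (length(neg) == m) return(c(pos, neg))
  c(pos, sample(neg, m))
}

#' Confusion-matrix metrics
#'
#' Counts and percentage metrics for binary predictions: accuracy
#' `ACC = (TP+TN)/n`, sensitivity `TPR = TP/(TP+FN)` and specificity
#' `SPC = TN/(TN+FP)`, all in percent. A ratio with a zero denominator is
#' reported as `NA` with the `degenerate` flag set, never as 0.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @param positive the positive-class value (default `1`; clinically, the
#'   complication class, so TPR is sensitivity to complications).
#' @return A `phaco_metrics` list: `tp`, `tn`, `fp`, `fn`, `n`, `acc`,
#'   `tpr`, `spc` (percent) and `degenerate`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) != length(y_pred))
    stop("shape error: y_true and y_pred differ in length")
  if (length(y_true) == 0) stop("empty label vectors")
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  n <- tp + tn + fp + fn
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- list(tp = tp, tn = tn, fp = fp, fn = fn, n = n,
              acc = ratio(tp + tn, n),
              tpr = ratio(tp, tp + fn),
              spc = ratio(tn, tn + fp))
  out$degenerate <- is.na(out$tpr) || is.na(out$spc)
  structure(out, class = "phaco_metrics")
}

# Stratified holdout split of a balanced index set: per class,
# round(m * test_fraction) records go to test (at least 1, at most m - 2).
stratified_split <- function(idx, labels, test_fraction) {
  classes <- sort(unique(labels[idx]))
  test <- integer()
  for (cl in classes) {
    ic <- idx[labels[idx] == cl]
    m <- length(ic)
    ntest <- min(max(1L, round(m * test_fraction)), m - 2L)
    if (ntest < 1L) stop("evaluation error: class too small to split")
    test <- c(test, sample(ic, ntest))
  }
  list(train = setdiff(idx, test), test = test)
}

#' Evaluate one feature subset under repeated balanced randomization
#'
#' Per randomization: balanced undersample, stratified train/test holdout,
#' fit, score. Each randomization owns an RNG stream derived from
#' `(seed, subset bitmask, randomization index)`, so results are identical
#' whether subsets are evaluated serially, chunked or in any order.
#'
#' @param X numeric feature matrix with canonical feature column names.
#' @param y binary labels (positive class = 1).
#' @param subset features to use: a bitmask, character names, or integer
#'   canonical indices.
#' @param spec a [classifier_spec()].
#' @param R number of randomizations.
#' @param test_fraction held-out fraction per randomization (default 1/3,
#'   mirroring the 2/3 train / 1/3 test protocol of the study).
#' @param seed master seed.
#' @param max_retries bounded redraws for degenerate randomizations.
#' @return An `evaluation_summary`: subset mask and names, classifier
#'   label, `R`, failures, and mean/SD of ACC, SPC, TPR over randomizations.
#' @export
evaluate_subset <- function(X, y, subset, spec = classifier_spec(),
                            R = 1000, test_fraction = 1/3, seed = 1L,
                            max_retries = 10L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is_count(R)) stop("R must be a positive integer")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  mask <- as_subset_mask(subset, colnames(X))
  cols <- subset_names(mask)
  cols <- intersect(cols, colnames(X))
  if (length(cols) == 0) stop("subset selects no columns of X")
  Xs <- X[, cols, drop = FALSE]

  acc <- spc <- tpr <- rep(NA_real_, R)
  failures <- 0L
  for (r in seq_len(R)) {
    done <- FALSE
    for (attempt in 0:max_retries) {
      res <- with_seed(derive_seed(seed, mask, r + R * attempt), {
        tryCatch({
          idx <- balanced_sample(y)
          sp <- stratified_split(idx, y, test_fraction)
          model <- spec$fit(Xs[sp$train, , drop = FALSE], y[sp$train])
          pred <- spec$predict(model, Xs[sp$test, , drop = FALSE])
          confusion_metrics(y[sp$test], pred)
        }, error = function(e) e)
      })
      if (!inherits(res, "error")) { done <- TRUE; break }
    }
    if (!done) { failures <- failures + 1L; next }
    acc[r] <- res$acc; spc[r] <- res$spc; tpr[r] <- res$tpr
  }
  ok <- !is.na(acc)
  structure(
    list(
      mask = mask, features = subset_names(mask), size = length(cols),
      classifier = spec$label, R = R, failures = failures,
      acc_mean = mean(acc[ok]), acc_sd = stats::sd(acc[ok]),
      spc_mean = mean(spc, na.rm = TRUE), spc_sd = stats::sd(spc, na.rm = TRUE),
      tpr_mean = mean(tpr, na.rm = TRUE), tpr_sd = stats::sd(tpr, na.rm = TRUE),
      seed = seed
    ),
    class = "evaluation_summary"
  )
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat("Balanced evaluation (", x$classifier, "), R = ", x$R, "\n", sep = "")
  cat("  subset [", x$size, "]: ", paste(x$features, collapse = " + "),
      "\n", sep = "")
  cat(sprintf("  ACC %.1f +/- %.1f  SPC %.1f +/- %.1f  TPR %.1f +/- %.1f\n",
              x$acc_mean, x$acc_sd, x$spc_mean, x$spc_sd,
              x$tpr_mean, x$tpr_sd))
  if (x$failures > 0) cat("  failed randomizations:", x$failures, "\n")
  invisible(x)
}
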