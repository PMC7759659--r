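# Exhaustive feature-subset search.
#
# A feature subset is a bitmask over the 22 canonical features (bit i-1 set
# iff canonical feature i is a member), the unit of the exhaustive
# peer-to-peer search: every non-empty subset of the non-excluded features
# is enumerated, evaluated under balanced randomization, ranked, and the
# per-feature occurrence counts above an accuracy threshold are tabulated.

#' Build a feature-subset bitmask
#'
#' @param features character vector of canonical feature names, or
#' @param indices integer vector of canonical feature positions (1-based).
#' @return The subset bitmask (integer).
#' @export
feature_subset <- function(features = NULL, indices = NULL) {
  nm <- cohort_schema()$features
  if (!is.null(features)) {
    bad <- setdiff(features, nm)
    if (length(bad) > 0) stop("unknown feature(s): ", paste(bad, collapse = ", "))
    indices <- match(features, nm)
  }
  if (is.null(indices) || length(indices) == 0)
    stop("a feature subset must be non-empty")
  if (any(indices < 1 | indices > length(nm) | indices != floor(indices)))
    stop("indices must be canonical feature positions 1..", length(nm))
  as.integer(sum(2^(unique(indices) - 1)))
}

# Normalise a subset argument: bitmask number, character names, or an
# object created by feature_subset(). Numbers are always read as bitmasks.
as_subset_mask <- function(subset, available = NULL) {
  if (is.character(subset)) return(feature_subset(features = subset))
  if (is.numeric(subset) && length(subset) == 1 && subset >= 1 &&
      subset == floor(subset) && subset < 2^22)
    return(as.integer(subset))
  stop("subset must be a bitmask or a character vector of feature names")
}

#' Member names of a subset bitmask
#'
#' @param mask subset bitmask.
#' @return Character vector of member features in canonical order.
#' @export
subset_names <- function(mask) {
  nm <- cohort_schema()$features
  nm[bitwAnd(as.integer(mask), bitwShiftL(1L, seq_along(nm) - 1L)) != 0L]
}

#' Subset size (popcount)
#'
#' Vectorised number of member features of each bitmask.
#'
#' @param mask vector of subset bitmasks.
#' @return Integer vector of sizes.
#' @export
subset_size <- function(mask) {
  mask <- as.integer(mask)
  out <- integer(length(mask))
  for (b in 0:21) out <- out + bitwAnd(bitwShiftR(mask, b), 1L)
  out
}

#' Count the subsets of an exhaustive search (closed form)
#'
#' `2^K' - 1` non-empty subsets of the `K'` non-excluded features, or the
#' binomial sum when a maximum subset size is imposed.
#'
#' @param k number of candidate features (default all 22).
#' @param exclude character vector of excluded features (only meaningful
#'   when `k` is the full canonical set).
#' @param max_size optional cap on subset size.
#' @return The subset count (double; exact for all desk-scale inputs).
#' @export
count_subsets <- function(k = 22, exclude = character(), max_size = NULL) {
  kp <- k - length(exclude)
  if (kp < 1) stop("empty-domain error: all features excluded")
  if (is.null(max_size)) return(2^kp - 1)
  sum(choose(kp, seq_len(min(max_size, kp))))
}

#' Enumerate feature subsets
#'
#' Yields every non-empty subset of the non-excluded canonical features
#' exactly once, in ascending-bitmask order (deterministic). Subsets are
#' materialised as a vector of bitmasks; the full 22-feature domain
#' (4,194,303 subsets) is supported but meant for long-running batch use —
#' desk-scale searches restrict the pool or cap the size.
#'
#' @param features candidate pool: character names or a count `K` (the
#'   first `K` canonical features). Default: all 22.
#' @param exclude features to drop from the pool.
#' @param max_size optional maximum subset size.
#' @return Integer vector of canonical bitmasks.
#' @export
enumerate_subsets <- function(features = NULL, exclude = character(),
                              max_size = NULL) {
  nm <- cohort_schema()$features
  if (is.null(features)) pool <- nm
  else if (is.numeric(features) && length(features) == 1)
    pool <- nm[seq_len(features)]
  else pool <- features
  bad <- setdiff(c(pool, exclude), nm)
  if (length(bad) > 0) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  pool <- setdiff(pool, exclude)
  kp <- length(pool)
  if (kp < 1) stop("empty-domain error: all features excluded")
  idx <- match(pool, nm)                     # canonical bit positions
  m <- seq_len(2^kp - 1)                     # reduced masks, ascending
  out <- numeric(length(m))
  for (j in seq_len(kp)) {
    bit <- (m %/% 2^(j - 1)) %% 2
    out <- out + bit * 2^(idx[j] - 1)
  }
  if (!is.null(max_size)) {
    keep <- rowSums(vapply(seq_len(kp),
                           function(j) (m %/% 2^(j - 1)) %% 2,
                           numeric(length(m)))) <= max_size
    out <- out[keep]
  }
  as.integer(out)
}

#' Search configuration
#'
#' @param features candidate pool (names or count), as in
#'   [enumerate_subsets()].
#' @param exclude excluded features (e.g. `"surgery_time"`).
#' @param spec a [classifier_spec()].
#' @param R randomizations per subset.
#' @param test_fraction held-out fraction.
#' @param threshold accuracy threshold tau, percent, for occurrence counts
#'   (strict `ACC > tau`).
#' @param top_n rows of the ranked report.
#' @param max_size optional subset-size cap.
#' @param seed master seed.
#' @return A `search_config` list.
#' @export
search_config <- function(features = NULL, exclude = character(),
                          spec = classifier_spec(), R = 50,
                          test_fraction = 1/3, threshold = 72, top_n = 10,
                          max_size = NULL, seed = 1L) {
  if (!(threshold > 0 && threshold < 100)) stop("threshold must be in (0, 100)")
  if (!is_count(top_n)) stop("top_n must be >= 1")
  structure(list(features = features, exclude = exclude, spec = spec, R = R,
                 test_fraction = test_fraction, threshold = threshold,
                 top_n = top_n, max_size = max_size, seed = seed),
            class = "search_config")
}

#' Exhaustive subset search
#'
#' Evaluates every enumerated subset with [evaluate_subset()]. Because each
#' subset's RNG streams are derived from `(seed, mask, index)`, any chunked
#' or parallel execution plan yields results identical to the serial order;
#' `chunks` exercises that contract. A subset whose evaluation fails is
#' recorded with `failed = TRUE`, never silently dropped.
#'
#' @param X encoded feature matrix (canonical column names).
#' @param y binary labels.
#' @param config a [search_config()].
#' @param chunks split the subset list into this many chunks, processed in
#'   reverse order (a determinism exercise; results are re-sorted by mask).
#' @param progress print a line every 500 subsets.
#' @return A `search_results` data.frame, one row per subset: `mask`,
#'   `size`, `features`, `classifier`, `R`, `acc_mean`, `acc_sd`,
#'   `spc_mean`, `spc_sd`, `tpr_mean`, `tpr_sd`, `failed`, `seed`.
#' @export
search_subsets <- function(X, y, config = search_config(), chunks = 1L,
                           progress = FALSE) {
  stopifnot(inherits(config, "search_config"))
  masks <- enumerate_subsets(config$features, config$exclude, config$max_size)
  # keep only subsets fully covered by X's columns
  covered <- vapply(masks, function(m)
    all(subset_names(m) %in% colnames(X)), logical(1))
  if (!all(covered))
    stop("encoded matrix does not cover the searched features: ",
         paste(setdiff(unlist(lapply(masks[!covered], subset_names)),
                       colnames(X)), collapse = ", "))
  chunk_id <- rep(seq_len(chunks), length.out = length(masks))
  rows <- vector("list", length(masks))
  done <- 0L
  for (ch in rev(seq_len(chunks))) {
    for (i in which(chunk_id == ch)) {
      m <- masks[i]
      s <- tryCatch(
        evaluate_subset(X, y, m, config$spec, config$R,
                        config$test_fraction, config$seed),
        error = function(e) e)
      rows[[i]] <- if (inherits(s, "error")) {
        data.frame(mask = m, size = subset_size(m),
                   features = paste(subset_names(m), collapse = "+"),
                   classifier = config$spec$label, R = config$R,
                   acc_mean = NA_real_, acc_sd = NA_real_,
                   spc_mean = NA_real_, spc_sd = NA_real_,
                   tpr_mean = NA_real_, tpr_sd = NA_real_,
                   failed = TRUE, seed = config$seed,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(mask = m, size = s$size,
                   features = paste(s$features, collapse = "+"),
                   classifier = s$classifier, R = s$R,
                   acc_mean = s$acc_mean, acc_sd = s$acc_sd,
                   spc_mean = s$spc_mean, spc_sd = s$spc_sd,
                   tpr_mean = s$tpr_mean, tpr_sd = s$tpr_sd,
                   failed = s$failures == s$R, seed = config$seed,
                   stringsAsFactors = FALSE)
      }
      done <- done + 1L
      if (progress && done %% 500L == 0L)
        message(done, " / ", length(masks), " subsets evaluated")
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$mask), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("search_results", "data.frame")
  res
}

#' Ranked top results
#'
#' Sorts by mean accuracy (descending); ties break by smaller subset size,
#' then ascending bitmask. Failed subsets are excluded.
#'
#' @param results a `search_results` data.frame.
#' @param n number of rows to keep (truncated to what exists).
#' @return The sorted head of `results`.
#' @export
top_results <- function(results, n = 10) {
  if (!is_count(n)) stop("n must be >= 1")
  ok <- results[!results$failed & !is.na(results$acc_mean), , drop = FALSE]
  if (nrow(ok) == 0) {
    warning("no successful subset evaluations to rank")
    return(ok)
  }
  ok <- ok[order(-ok$acc_mean, ok$size, ok$mask), , drop = FALSE]
  utils::head(ok, n)
}

#' Indicator-style report table
#'
#' Renders ranked results as 0/1 feature-indicator rows plus the mean ACC,
#' one column per canonical feature (the layout of the published
#' configuration tables).
#'
#' @param results a `search_results` data.frame (already ranked or not).
#' @param n rows to render (ranked by [top_results()]).
#' @return data.frame of 22 indicator columns plus `acc`.
#' @export
format_indicator_table <- function(results, n = 10) {
  top <- top_results(results, n)
  nm <- cohort_schema()$features
  ind <- t(vapply(top$mask, function(m) as.integer(nm %in% subset_names(m)),
                  integer(length(nm))))
  colnames(ind) <- nm
  out <- as.data.frame(ind)
  out$acc <- round(top$acc_mean, 1)
  out
}

#' Feature-occurrence counts above an accuracy threshold
#'
#' For each canonical feature, the number of qualifying subsets (mean ACC
#' strictly greater than `tau`, in percent) that contain it. Failed subsets
#' never qualify.
#'
#' @param results a `search_results` data.frame.
#' @param tau accuracy threshold in percent (default 72).
#' @return An `occurrence_table`: named integer vector over the 22
#'   canonical features, with attribute `"n_qualifying"`.
#' @export
occurrence_counts <- function(results, tau = 72) {
  if (!(tau > 0 && tau < 100)) stop("tau must be in (0, 100)")
  nm <- cohort_schema()$features
  qual <- results$mask[!results$failed & !is.na(results$acc_mean) &
                         results$acc_mean > tau]
  counts <- stats::setNames(integer(length(nm)), nm)
  for (i in seq_along(nm)) {
    bit <- bitwShiftL(1L, i - 1L)
    counts[i] <- sum(bitwAnd(as.integer(qual), bit) != 0L)
  }
  structure(counts, n_qualifying = length(qual), class = "occurrence_table")
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Feature occurrences among", attr(x, "n_qualifying"),
      "qualifying subsets:\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Write search results to a TSV ledger
#'
#' @param results a `search_results` data.frame.
#' @param path output path.
#' @param append append to an existing ledger (resumable by bitmask).
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, append = FALSE) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, append = append,
                     col.names = !append || !file.exists(path))
  invisible(path)
}
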