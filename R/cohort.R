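#' Construct a cohort table from a data.frame
#'
#' Validates a patient-level table against the canonical schema (see
#' [cohort_schema()]) and returns it as a `cohort_table`: 22 feature columns
#' in canonical order, a binary `complication` label and a unique `id`.
#'
#' @param df data.frame with the canonical columns (any order, any case).
#' @param strict logical; if `TRUE` (default) any invariant violation is an
#'   error. If `FALSE`, offending rows are flagged in the validation report
#'   (attribute `"validation"`) and missing numeric values are imputed by
#'   the column median, categorical ones by the column mode.
#' @return A `cohort_table` (data.frame with columns `id`, the 22 features,
#'   `complication`), with a `"validation"` attribute in permissive mode.
#' @export
as_cohort_table <- function(df, strict = TRUE) {
  sch <- cohort_schema()
  wanted <- c("id", sch$features, "complication")

  nm <- tolower(names(df))
  missing_cols <- setdiff(wanted, nm)
  if (length(missing_cols) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(nm, wanted)
  if (length(extra) > 0)
    warning("ignoring non-canonical column(s): ", paste(extra, collapse = ", "))
  names(df) <- nm
  df <- df[, wanted, drop = FALSE]

  issues <- data.frame(row = integer(), id = character(), column = character(),
                       problem = character(), stringsAsFactors = FALSE)
  note <- function(rows, col, problem) {
    if (length(rows) == 0) return()
    issues <<- rbind(issues, data.frame(
      row = rows, id = as.character(df$id[rows]), column = col,
      problem = problem, stringsAsFactors = FALSE))
  }

  # numeric features: coerce, parse-check, range-check
  for (f in names(sch$numeric)) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(!is.na(v) & v != "" & is.na(parsed))
      if (length(bad) > 0) {
        if (strict)
          stop("parse error: non-numeric value in column '", f,
               "' at row id(s): ",
               paste(utils::head(df$id[bad], 5), collapse = ", "))
        note(bad, f, "non-numeric")
      }
      v <- parsed
    }
    miss <- which(is.na(v))
    if (length(miss) > 0) {
      if (strict)
        stop("missing value in numeric column '", f, "' at row id(s): ",
             paste(utils::head(df$id[miss], 5), collapse = ", "))
      note(miss, f, "missing (imputed by median)")
      v[miss] <- stats::median(v, na.rm = TRUE)
    }
    rng <- sch$numeric[[f]]
    out <- which(v < rng[1] | v > rng[2])
    if (length(out) > 0) {
      if (strict)
        stop("value out of plausibility range [", rng[1], ", ", rng[2],
             "] in column '", f, "' at row id(s): ",
             paste(utils::head(df$id[out], 5), collapse = ", "))
      note(out, f, "out of range")
    }
    df[[f]] <- v
  }

  # categorical features: level-check, impute by mode in permissive mode
  for (f in names(sch$categorical)) {
    v <- as.character(df[[f]])
    lv <- sch$categorical[[f]]
    miss <- which(is.na(v) | v == "")
    bad <- which(!is.na(v) & v != "" & !(v %in% lv))
    if (length(bad) > 0) {
      if (strict)
        stop("unknown level '", v[bad[1]], "' in categorical column '", f,
             "' (allowed: ", paste(lv, collapse = ", "), ")")
      note(bad, f, "unknown level (imputed by mode)")
      v[bad] <- NA_character_
    }
    if (length(miss) > 0) {
      if (strict)
        stop("missing value in categorical column '", f, "' at row id(s): ",
             paste(utils::head(df$id[miss], 5), collapse = ", "))
      note(miss, f, "missing (imputed by mode)")
    }
    fill <- which(is.na(v))
    if (length(fill) > 0) {
      tab <- table(v[v %in% lv])
      v[fill] <- names(tab)[which.max(tab)]
    }
    df[[f]] <- v
  }

  # label and ids
  lab <- suppressWarnings(as.numeric(df$complication))
  badlab <- which(!(lab %in% c(0, 1)))
  if (length(badlab) > 0) {
    if (strict)
      stop("complication label must be 0 or 1; offending row id(s): ",
           paste(utils::head(df$id[badlab], 5), collapse = ", "))
    note(badlab, "complication", "label not in {0,1} (set to 0)")
    lab[badlab] <- 0
  }
  df$complication <- as.integer(lab)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("record ids are not unique (e.g. '",
         df$id[duplicated(df$id)][1], "')")

  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  attr(df, "schema_version") <- sch$version
  if (!strict) attr(df, "validation") <- issues
  df
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, point-decimal cohort file whose header
#' contains the canonical column names (case-insensitive, any order) and
#' validates it against the schema.
#'
#' @param path path to a CSV file.
#' @param strict see [as_cohort_table()].
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_cohort_table(df, strict = strict)
}

#' Write a cohort table to CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips bit-identically.
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  out <- as.data.frame(cohort)
  for (f in names(out)) {
    if (is.double(out[[f]])) {
      s <- formatC(out[[f]], digits = 17, format = "g")
      out[[f]] <- trimws(s)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build an encoding specification for categorical features
#'
#' Assigns integer codes `0 .. L-1` to each categorical feature's levels in
#' sorted level order (deterministic). With `open = TRUE` the level sets are
#' taken from the data at encoding time instead of the schema.
#'
#' @param open logical; open specs learn levels from the data.
#' @return An `encoding_spec` object.
#' @export
encoding_spec <- function(open = FALSE) {
  sch <- cohort_schema()
  levels <- if (open) NULL else lapply(sch$categorical, sort)
  structure(list(open = open, levels = levels), class = "encoding_spec")
}

#' Encode a cohort into a numeric feature matrix
#'
#' Numeric features pass through unchanged. Categorical features become
#' integer codes in sorted level order (default) or 0/1 indicator columns
#' (`encoding = "indicator"`). The returned object carries a complete
#' column-to-feature map and the per-feature code assignment, so encoded
#' categories can be decoded back exactly.
#'
#' @param cohort a `cohort_table` (or data.frame with the feature columns).
#' @param encoding `"ordinal"` (one column per feature) or `"indicator"`.
#' @param spec an [encoding_spec()]; closed by default.
#' @return A `feature_matrix`: list with `X` (numeric matrix, n x p),
#'   `column_map` (data.frame `column`, `feature`), `encoding`,
#'   `codes` (per-categorical named code vectors) and `y`
#'   (the complication labels, if present in `cohort`).
#' @export
encode_features <- function(cohort, encoding = c("ordinal", "indicator"),
                            spec = encoding_spec()) {
  encoding <- match.arg(encoding)
  sch <- cohort_schema()
  stopifnot(inherits(spec, "encoding_spec"))
  df <- as.data.frame(cohort)
  missing_cols <- setdiff(sch$features, names(df))
  if (length(missing_cols) > 0)
    stop("cohort lacks feature column(s): ", paste(missing_cols, collapse = ", "))

  cols <- list()
  map_col <- character()
  map_feat <- character()
  codes <- list()

  for (f in sch$features) {
    if (f %in% names(sch$numeric)) {
      v <- as.numeric(df[[f]])
      if (anyNA(v)) stop("missing numeric values in '", f, "'; validate first")
      cols[[length(cols) + 1L]] <- v
      map_col <- c(map_col, f); map_feat <- c(map_feat, f)
    } else {
      v <- as.character(df[[f]])
      lv <- if (spec$open) sort(unique(v)) else spec$levels[[f]]
      unseen <- setdiff(unique(v), lv)
      if (length(unseen) > 0)
        stop("encoding error: unseen level(s) in closed spec for '", f,
             "': ", paste(unseen, collapse = ", "))
      code <- stats::setNames(seq_along(lv) - 1L, lv)
      codes[[f]] <- code
      if (encoding == "ordinal") {
        cols[[length(cols) + 1L]] <- as.numeric(code[v])
        map_col <- c(map_col, f); map_feat <- c(map_feat, f)
      } else {
        for (l in lv) {
          cols[[length(cols) + 1L]] <- as.numeric(v == l)
          map_col <- c(map_col, paste(f, l, sep = ".")); map_feat <- c(map_feat, f)
        }
      }
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- map_col
  structure(
    list(
      X = X,
      column_map = data.frame(column = map_col, feature = map_feat,
                              stringsAsFactors = FALSE),
      encoding = encoding,
      codes = codes,
      y = if ("complication" %in% names(df)) as.integer(df$complication) else NULL
    ),
    class = "feature_matrix"
  )
}

#' Decode encoded categorical columns back to level labels
#'
#' Inverse of the ordinal encoding in [encode_features()]; indicator
#' encodings are decoded by the active column per feature.
#'
#' @param fm a `feature_matrix`.
#' @return data.frame of the categorical features as character columns.
#' @export
decode_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- list()
  for (f in names(fm$codes)) {
    code <- fm$codes[[f]]
    if (fm$encoding == "ordinal") {
      v <- fm$X[, f]
      out[[f]] <- names(code)[match(v, code)]
    } else {
      colsel <- fm$column_map$column[fm$column_map$feature == f]
      sub <- fm$X[, colsel, drop = FALSE]
      out[[f]] <- names(code)[max.col(sub, ties.method = "first")]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
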