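# Pipeline wiring: a single entry point that runs the requested stages
# (generate -> search -> predict-time -> report) into a run directory,
# stamping every run with its config fingerprint and master seed so that a
# rerun with the same config is byte-identical for the deterministic
# stages.

#' Pipeline run configuration
#'
#' @param stages character vector, any of `"generate"`, `"search"`,
#'   `"predict_time"`, `"report"` (in execution order).
#' @param n cohort size for the generate stage.
#' @param seed master seed; every stage derives its streams from it.
#' @param cohort_path optional existing cohort CSV (when `"generate"` is not
#'   among the stages).
#' @param generator optional `generator_params` (default: calibrated
#'   population defaults).
#' @param search optional [search_config()]; its `seed` is overridden by
#'   the master seed. Default: a desk-scale pool (the three ground-truth
#'   risk features plus age, sex, iop, acd), diaglinear, R = 20.
#' @param time_pool candidate features for the time-prediction scan;
#'   all their non-empty subsets are scanned.
#' @param network a [network_spec()].
#' @param out_dir run directory (created if needed).
#' @return A `run_config`.
#' @export
run_config <- function(stages = c("generate", "search", "predict_time",
                                  "report"),
                       n = 1229, seed = 1L, cohort_path = NULL,
                       generator = NULL, search = NULL,
                       time_pool = c("iol_power", "axial_length",
                                     "kind_of_surgeon", "age", "iop"),
                       network = network_spec(),
                       out_dir = "phacorisk_run") {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(search))
    search <- search_config(
      features = c("kind_of_surgeon", "axial_length", "iol_power",
                   "age", "sex", "iop", "acd"),
      spec = classifier_spec("discriminant", "diaglinear"),
      R = 20, seed = seed)
  search$seed <- seed
  structure(list(stages = stages, n = n, seed = as.integer(seed),
                 cohort_path = cohort_path, generator = generator,
                 search = search, time_pool = time_pool, network = network,
                 out_dir = out_dir),
            class = "run_config")
}

# Serializable fingerprint of a run config (functions and environments are
# reduced to their deparsed form before hashing).
config_fingerprint <- function(config) {
  flat <- rapply(unclass(config), function(x) {
    if (is.function(x)) paste(deparse(x), collapse = "") else x
  }, how = "replace")
  fnv1a_hash(paste(utils::capture.output(utils::str(flat)), collapse = "\n"))
}

#' Run the pipeline
#'
#' Executes the configured stages in order. Artifacts written to the run
#' directory: `cohort.csv` and `generator_params.json` (generate),
#' `search_results.tsv`, `top_results.tsv`, `top_results_no_time.tsv` and
#' `occurrence_counts.tsv` (search), `time_scan.tsv` and
#' `time_comparison.json` (predict_time), `report.md` (report), plus a
#' `manifest.json` stamping every artifact with the config fingerprint and
#' master seed. A stage failure aborts with the partial artifacts and a
#' `failure.json` manifest preserved.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(config)
  artifacts <- character()
  path <- function(f) file.path(config$out_dir, f)
  fail <- function(stage, e) {
    jsonlite::write_json(
      list(failed_stage = stage, error = conditionMessage(e),
           artifacts = artifacts, fingerprint = fp, seed = config$seed),
      path("failure.json"), auto_unbox = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  cohort <- NULL
  if ("generate" %in% config$stages) {
    tryCatch({
      gp <- config$generator %||% default_generator_params()
      cohort <- generate_cohort(gp, seed = config$seed, n = config$n)
      write_cohort(cohort, path("cohort.csv"))
      snap <- unclass(gp)
      snap$fingerprint <- fp
      snap$seed <- config$seed
      jsonlite::write_json(snap, path("generator_params.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      artifacts <- c(artifacts, "cohort.csv", "generator_params.json")
    }, error = function(e) fail("generate", e))
  }
  if (is.null(cohort) && !is.null(config$cohort_path))
    cohort <- tryCatch(read_cohort(config$cohort_path),
                       error = function(e) fail("load_cohort", e))

  search_out <- NULL
  if ("search" %in% config$stages) {
    tryCatch({
      if (is.null(cohort)) stop("no cohort available (generate or cohort_path)")
      fm <- encode_features(cohort)
      res <- search_subsets(fm$X, fm$y, config$search)
      write_results_tsv(res, path("search_results.tsv"))
      utils::write.table(format_indicator_table(res, config$search$top_n),
                         path("top_results.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      no_time <- res[bitwAnd(as.integer(res$mask),
                             feature_subset("surgery_time")) == 0L, ,
                     drop = FALSE]
      if (nrow(no_time) > 0)
        utils::write.table(format_indicator_table(no_time, config$search$top_n),
                           path("top_results_no_time.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
      occ <- occurrence_counts(res, config$search$threshold)
      utils::write.table(
        data.frame(feature = names(occ), count = as.integer(occ)),
        path("occurrence_counts.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      artifacts <- c(artifacts, "search_results.tsv", "top_results.tsv",
                     if (nrow(no_time) > 0) "top_results_no_time.tsv",
                     "occurrence_counts.tsv")
      search_out <- res
    }, error = function(e) fail("search", e))
  }

  scan <- NULL
  if ("predict_time" %in% config$stages) {
    tryCatch({
      if (is.null(cohort)) stop("no cohort available (generate or cohort_path)")
      fm <- encode_features(cohort)
      Xin <- fm$X[, setdiff(colnames(fm$X), "surgery_time"), drop = FALSE]
      configs <- enumerate_subsets(config$time_pool)
      scan <- scan_configurations(Xin, cohort$surgery_time, configs,
                                  config$network, seed = config$seed,
                                  strata = fm$y)
      write_results_tsv(scan, path("time_scan.tsv"))
      best <- attr(scan, "best")
      if (!is.null(best)) {
        m <- as.integer(best$mask)
        test <- with_seed(derive_seed(config$seed, 0, 0),
                          stratified_split(seq_len(nrow(Xin)), fm$y, 1/3)$test)
        train <- setdiff(seq_len(nrow(Xin)), test)
        Xm <- mask_inputs(Xin, m)
        net <- fit_time_network(Xm[train, , drop = FALSE],
                                cohort$surgery_time[train], config$network,
                                seed = derive_seed(config$seed, m, 1))
        cmp <- compare_times(predict(net, Xm[test, , drop = FALSE]),
                             cohort$surgery_time[test])
        cmp$configuration <- best$features
        jsonlite::write_json(cmp, path("time_comparison.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        artifacts <- c(artifacts, "time_comparison.json")
      }
      artifacts <- c(artifacts, "time_scan.tsv")
    }, error = function(e) fail("predict_time", e))
  }

  if ("report" %in% config$stages) {
    tryCatch({
      lines <- c(
        "# phacorisk run report", "",
        paste0("- config fingerprint: `", fp, "`"),
        paste0("- master seed: ", config$seed), "")
      if (!is.null(cohort)) {
        lines <- c(lines,
          paste0("- cohort: n = ", nrow(cohort), ", complications = ",
                 sum(cohort$complication)),
          paste0("- surgery time: ",
                 sprintf("%.2f +/- %.2f min", mean(cohort$surgery_time),
                         stats::sd(cohort$surgery_time))), "")
      }
      if (!is.null(search_out)) {
        top <- top_results(search_out, min(3, nrow(search_out)))
        lines <- c(lines, "## Best feature subsets (mean ACC, %)", "",
                   sprintf("- %s: %.1f", top$features, top$acc_mean), "")
      }
      if (!is.null(scan)) {
        best <- attr(scan, "best")
        if (!is.null(best))
          lines <- c(lines, "## Surgery-time prediction", "",
                     sprintf("- best configuration: %s", best$features),
                     sprintf("- max abs test error: %.2f min (RMSE %.2f)",
                             best$max_abs_error, best$rmse), "")
      }
      writeLines(lines, path("report.md"))
      artifacts <- c(artifacts, "report.md")
    }, error = function(e) fail("report", e))
  }

  manifest <- list(fingerprint = fp, seed = config$seed,
                   stages = config$stages, artifacts = artifacts)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
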