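#' Canonical cohort schema
#'
#' The pipeline operates on patient-level records with 22 clinical features
#' (the fixed, canonical column order used throughout: subset bitmasks,
#' report tables and encoded matrices all index features in this order),
#' a binary intraoperative-complication label and a unique record id.
#'
#' Numeric features carry plausibility ranges used for validation; the
#' ranges for most features are the observed ranges of the study population
#' the generator emulates. Categorical features carry their closed level
#' sets. Keratometry is stored as flattest (`k1`) and steepest (`k2`)
#' meridian plus their mean (`mean_k`).
#'
#' @return A list with elements `features` (character vector of the 22
#'   canonical names, in order), `numeric` (named list of `c(low, high)`
#'   plausibility ranges), `categorical` (named list of level vectors),
#'   `extra` (non-feature columns: `id`, `complication`) and `version`.
#' @export
#' @examples
#' sch <- cohort_schema()
#' sch$features
cohort_schema <- function() {
  numeric_ranges <- list(
    age                    = c(10, 94),       # years
    bcva                   = c(0, 0.95),      # decimal acuity
    sphere                 = c(-30, 8.5),     # dioptres
    cylinder               = c(-5, 4.5),      # dioptres
    spherical_equivalent   = c(-32.5, 10.75), # dioptres (sphere + cyl/2)
    iop                    = c(8, 24),        # mmHg
    iol_power              = c(-7, 34),       # dioptres
    axial_length           = c(17, 35.82),    # mm
    k1                     = c(30, 56),       # dioptres, flattest meridian
    k2                     = c(30, 56),       # dioptres, steepest meridian
    mean_k                 = c(30, 56),       # dioptres
    acd                    = c(2.23, 4.03),   # mm, from epithelium
    endothelial_cell_count = c(1293, 3213),   # cells/mm^2
    surgery_time           = c(5, 85)         # minutes
  )
  categorical_levels <- list(
    sex = c("female", "male"),
    eye = c("left", "right"),
    systemic_disease = c(
      "none", "bph", "niddm", "hypertension", "heart_condition",
      "respiratory", "iddm", "previous_stroke", "other"),
    ocular_disease = c(
      "none", "glaucoma", "pex", "dr", "pdr", "amblyopia", "maculopathy",
      "corneal_dystrophy", "trauma_congenital", "retinal_laser",
      "post_refractive"),
    cataract_type = c(
      "total", "cortico_nuclear", "subcapsular",
      "cortico_nuclear_subcapsular"),
    anesthesia = c("general", "topical", "subtenon", "peribulbar"),
    extra_device = c("none", "iris_hooks", "malyugin_ring", "trypan_blue"),
    kind_of_surgeon = c("trained", "resident")
  )
  features <- c(
    "age", "sex", "eye", "systemic_disease", "ocular_disease",
    "cataract_type", "bcva", "sphere", "cylinder", "spherical_equivalent",
    "iop", "iol_power", "axial_length", "k1", "k2", "mean_k", "acd",
    "endothelial_cell_count", "anesthesia", "surgery_time", "extra_device",
    "kind_of_surgeon")
  stopifnot(length(features) == 22L)
  structure(
    list(
      features = features,
      numeric = numeric_ranges,
      categorical = categorical_levels,
      extra = c("id", "complication"),
      version = "1.0"
    ),
    class = "cohort_schema"
  )
}

#' Names of the canonical features
#'
#' @param exclude optional character vector of features to drop.
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function(exclude = character()) {
  nm <- cohort_schema()$features
  bad <- setdiff(exclude, nm)
  if (length(bad) > 0)
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  setdiff(nm, exclude)
}

#' Write the canonical schema to a JSON config file
#'
#' Publishes the versioned cohort schema (feature order, numeric ranges,
#' categorical level sets) so that external tools can validate cohort CSVs.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema_json <- function(path) {
  jsonlite::write_json(unclass(cohort_schema()), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Intraoperative complication categories
#'
#' The six recorded complication categories with their case counts in the
#' study population (73 complications in total). Percentages are recomputed
#' from the counts, not transcribed.
#'
#' @return A data.frame with columns `category`, `count` and `percent`
#'   (rounded to two decimals).
#' @export
complication_categories <- function() {
  counts <- c(
    capsular_tear_no_vitrectomy       = 19L,
    capsular_tear_with_vitrectomy     = 32L,
    hypertension_iris_prolapse        = 13L,
    conversion_to_extracapsular       = 4L,
    nucleus_drop                      = 4L,
    vitreous_loss_no_tear             = 1L
  )
  data.frame(
    category = names(counts),
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / sum(counts), 2),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
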