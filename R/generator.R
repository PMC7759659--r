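# Synthetic cohort generator.
#
# Emulates the published population structure of a 1,229-eye teaching-
# hospital phacoemulsification cohort: numeric feature marginals given as
# mean / SD / range, categorical level frequencies given as counts, an
# overall complication prevalence of 73/1,229 stratified by surgeon type
# (48 complications under trained surgeons, 25 under residents), and a
# surgery-time model driven by surgeon type, axial-length and IOL-power
# deviation, complication status and noise. Only marginals and the stated
# risk structure are emulated; no joint distribution of the clinical data
# is claimed.

.phaco_cache <- new.env(parent = emptyenv())

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler: exact truncated-normal marginals, vectorised, and
#' usable with correlated uniforms for optional copula dependence.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal (`sd > 0`).
#' @param low,high truncation bounds (`low < high`).
#' @param u optional vector of `n` uniforms on (0,1) to transform instead of
#'   drawing fresh ones (used for correlated sampling).
#' @return Numeric vector of `n` values in `[low, high]`.
#' @export
sample_truncated_normal <- function(n, mean, sd, low, high, u = NULL) {
  if (!is_count(n, min = 0)) stop("n must be a non-negative integer")
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  if (!(low < high)) stop("parameter error: need low < high")
  plo <- stats::pnorm(low, mean, sd)
  phi <- stats::pnorm(high, mean, sd)
  if (is.null(u)) u <- stats::runif(n)
  x <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  clamp(x, low, high)
}

#' Closed-form mean of a truncated normal
#'
#' @inheritParams sample_truncated_normal
#' @return The expectation of the truncated distribution.
#' @export
truncated_normal_mean <- function(mean, sd, low, high) {
  a <- (low - mean) / sd
  b <- (high - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Generator parameters
#'
#' Builds the parameter set of the synthetic-cohort generator. All defaults
#' encode the published population tables: numeric features as truncated
#' normals (target mean, SD and range), categorical features as level
#' frequencies renormalised from the printed counts, a logistic risk model
#' on surgeon type and on the absolute deviations of axial length and IOL
#' power from their population centres, and an additive surgery-time model.
#'
#' Three quantities are left for calibration (see [calibrate_generator()]):
#' the risk-model intercept (solved so the expected complication count is
#' `prevalence * n`), and the time model's baseline and global effect scale
#' (solved so the realised clipped surgery-time marginal matches its target
#' mean and SD). Numeric sampling locations are also adjusted so that the
#' *truncated* means equal the target means.
#'
#' @param n default cohort size.
#' @param risk_model,time_model optional lists overriding individual
#'   components (see Details in the package vignette).
#' @param al_iol_correlation Gaussian-copula correlation between axial
#'   length and IOL power (clinically negative; off, i.e. 0, by default).
#' @param calibrate logical; run [calibrate_generator()] before returning.
#' @return A `generator_params` object.
#' @export
generator_params <- function(n = 1229,
                             risk_model = list(),
                             time_model = list(),
                             al_iol_correlation = 0,
                             calibrate = TRUE) {
  numeric <- list(
    age                    = list(mean = 70.2,   sd = 10.3,   low = 10,    high = 94),
    bcva                   = list(mean = 0.27,   sd = 0.19,   low = 0,     high = 0.95),
    sphere                 = list(mean = -1.36,  sd = 4.27,   low = -30,   high = 8.5),
    cylinder               = list(mean = -0.18,  sd = 0.95,   low = -5,    high = 4.5),
    iop                    = list(mean = 15.25,  sd = 2.21,   low = 8,     high = 24),
    iol_power              = list(mean = 20.15,  sd = 5.59,   low = -7,    high = 34),
    axial_length           = list(mean = 23.89,  sd = 2.08,   low = 17,    high = 35.82),
    mean_k                 = list(mean = 44.16,  sd = 1.74,   low = 33.24, high = 52.12),
    acd                    = list(mean = 3.09,   sd = 0.48,   low = 2.23,  high = 4.03),
    endothelial_cell_count = list(mean = 2410.59, sd = 294.99, low = 1293, high = 3213)
  )
  # Level frequencies renormalised from printed counts (the printed counts,
  # not the printed percentages, are treated as primary data; some table
  # totals differ slightly from the cohort size).
  counts_to_freq <- function(x) x / sum(x)
  categorical <- list(
    sex = counts_to_freq(c(female = 672, male = 557)),
    eye = counts_to_freq(c(left = 653, right = 578)),
    systemic_disease = counts_to_freq(c(
      none = 226, bph = 15, niddm = 37, hypertension = 297,
      heart_condition = 27, respiratory = 47, iddm = 24,
      previous_stroke = 8, other = 23)),
    ocular_disease = counts_to_freq(c(
      none = 681, glaucoma = 122, pex = 18, dr = 11, pdr = 52,
      amblyopia = 19, maculopathy = 138, corneal_dystrophy = 80,
      trauma_congenital = 19, retinal_laser = 5, post_refractive = 6)),
    cataract_type = counts_to_freq(c(
      total = 62, cortico_nuclear = 765, subcapsular = 76,
      cortico_nuclear_subcapsular = 326)),
    anesthesia = counts_to_freq(c(
      general = 4, topical = 203, subtenon = 269, peribulbar = 453)),
    # not tabulated in the source population; chosen defaults, documented
    # in the methods vignette (devices are rare and risk-independent here)
    extra_device = c(none = 0.92, iris_hooks = 0.03,
                     malyugin_ring = 0.025, trypan_blue = 0.025),
    kind_of_surgeon = counts_to_freq(c(trained = 1043, resident = 181))
  )

  rm_default <- list(
    intercept = NA_real_,        # calibrated
    surgeon = 1.2,               # log-odds, resident vs trained
    al = 0.12,                   # per mm of |AL - al_center|
    al_center = 23.89,
    iol = 0.05,                  # per D of |IOL - iol_center|
    iol_center = 20.15,
    prevalence = 73 / 1229
  )
  tm_default <- list(
    baseline = NA_real_,         # calibrated, minutes
    scale = NA_real_,            # calibrated global multiplier on effects
    resident = 15,               # minutes, surgeon-in-training increment
    complication = 3,            # minutes, complication increment
    al = 4.0,                    # minutes per mm of |AL - al_center|
    al_center = 23.89,
    iol = 1.71,                  # minutes per D of |IOL - iol_center|
    iol_center = 20.15,
    noise_sd = 1.2,              # minutes, irreducible noise
    target_mean = 17.58,
    target_sd = 9.42,
    low = 5, high = 85
  )
  rm <- utils::modifyList(rm_default, risk_model)
  tm <- utils::modifyList(tm_default, time_model)

  p <- structure(
    list(
      n = n,
      numeric = numeric,
      categorical = categorical,
      corneal_astigmatism = list(sd = 1.0, max = 6),
      al_iol_correlation = al_iol_correlation,
      risk_model = rm,
      time_model = tm,
      calibration = list(n_mc = 200000L, seed = 760309L),
      calibrated = FALSE
    ),
    class = "generator_params"
  )
  if (calibrate) p <- calibrate_generator(p) else {
    # uncalibrated params still need sampling locations
    for (f in names(p$numeric)) p$numeric[[f]]$mu <- p$numeric[[f]]$mean
    if (is.na(p$time_model$baseline)) p$time_model$baseline <- p$time_model$target_mean
    if (is.na(p$time_model$scale)) p$time_model$scale <- 1
  }
  p
}

#' Default, fully calibrated generator parameters
#'
#' Cached so the (deterministic, Monte Carlo based) calibration runs once
#' per session.
#'
#' @return A calibrated `generator_params` object with `n = 1229`.
#' @export
default_generator_params <- function() {
  if (is.null(.phaco_cache$default_params))
    .phaco_cache$default_params <- generator_params()
  .phaco_cache$default_params
}

# Sample the 22 features (without outcomes) for n records under `params`.
# Uses the current RNG state; callers seed.
sample_features <- function(params, n) {
  nm <- params$numeric
  draw <- function(f) {
    sample_truncated_normal(n, nm[[f]]$mu, nm[[f]]$sd, nm[[f]]$low, nm[[f]]$high)
  }
  age <- draw("age"); bcva <- draw("bcva")
  sphere <- draw("sphere"); cylinder <- draw("cylinder")
  iop <- draw("iop"); mean_k <- draw("mean_k"); acd <- draw("acd")
  ecc <- draw("endothelial_cell_count")

  rho <- params$al_iol_correlation
  if (rho != 0) {
    # Gaussian copula: exact truncated marginals, correlated ranks
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    al <- sample_truncated_normal(n, nm$axial_length$mu, nm$axial_length$sd,
                                  nm$axial_length$low, nm$axial_length$high,
                                  u = stats::pnorm(z1))
    iol <- sample_truncated_normal(n, nm$iol_power$mu, nm$iol_power$sd,
                                   nm$iol_power$low, nm$iol_power$high,
                                   u = stats::pnorm(z2))
  } else {
    al <- draw("axial_length")
    iol <- draw("iol_power")
  }

  # derived optics: spherical equivalent is its clinical definition;
  # keratometry meridians straddle the sampled mean K by a half astigmatism
  sch <- cohort_schema()
  se <- clamp(sphere + cylinder / 2, sch$numeric$spherical_equivalent[1],
              sch$numeric$spherical_equivalent[2])
  ca <- params$corneal_astigmatism
  astig <- pmin(abs(stats::rnorm(n, 0, ca$sd)), ca$max)
  k1 <- mean_k - astig / 2
  k2 <- mean_k + astig / 2

  cat_draw <- function(f) {
    fr <- params$categorical[[f]]
    sample(names(fr), n, replace = TRUE, prob = fr)
  }
  data.frame(
    age = age, sex = cat_draw("sex"), eye = cat_draw("eye"),
    systemic_disease = cat_draw("systemic_disease"),
    ocular_disease = cat_draw("ocular_disease"),
    cataract_type = cat_draw("cataract_type"),
    bcva = bcva, sphere = sphere, cylinder = cylinder,
    spherical_equivalent = se, iop = iop, iol_power = iol,
    axial_length = al, k1 = k1, k2 = k2, mean_k = mean_k, acd = acd,
    endothelial_cell_count = ecc, anesthesia = cat_draw("anesthesia"),
    extra_device = cat_draw("extra_device"),
    kind_of_surgeon = cat_draw("kind_of_surgeon"),
    stringsAsFactors = FALSE
  )
}

# Linear predictor of the complication risk model, excluding the intercept.
risk_eta0 <- function(features, rm) {
  needed <- c("kind_of_surgeon", "axial_length", "iol_power")
  missing_f <- setdiff(needed, names(features))
  if (length(missing_f) > 0)
    stop("config error: risk model references unknown feature(s): ",
         paste(missing_f, collapse = ", "))
  rm$surgeon * (features$kind_of_surgeon == "resident") +
    rm$al * abs(features$axial_length - rm$al_center) +
    rm$iol * abs(features$iol_power - rm$iol_center)
}

# Deterministic (noise-free, pre-clipping) surgery-time effect terms,
# before baseline shift and global scaling.
time_terms <- function(features, label, tm) {
  needed <- c("kind_of_surgeon", "axial_length", "iol_power")
  missing_f <- setdiff(needed, names(features))
  if (length(missing_f) > 0)
    stop("config error: time model references unknown feature(s): ",
         paste(missing_f, collapse = ", "))
  tm$resident * (features$kind_of_surgeon == "resident") +
    tm$complication * label +
    tm$al * abs(features$axial_length - tm$al_center) +
    tm$iol * abs(features$iol_power - tm$iol_center)
}

#' Calibrate a generator parameter set
#'
#' Three deterministic calibrations, performed on a fixed-seed Monte Carlo
#' sample (`params$calibration`) independent of any user seed:
#' \enumerate{
#'   \item numeric sampling locations `mu` solved (closed form, per feature)
#'     so the truncated-normal mean equals the target mean;
#'   \item risk intercept solved so the mean logistic probability equals the
#'     target prevalence;
#'   \item surgery-time baseline and effect scale solved so the realised
#'     (clipped) time marginal matches its target mean and SD.
#' }
#'
#' @param params a `generator_params` object.
#' @return The calibrated `generator_params`.
#' @export
calibrate_generator <- function(params) {
  stopifnot(inherits(params, "generator_params"))

  # 1. location adjustment so truncated means hit targets
  for (f in names(params$numeric)) {
    pf <- params$numeric[[f]]
    g <- function(mu) truncated_normal_mean(mu, pf$sd, pf$low, pf$high) - pf$mean
    sol <- stats::uniroot(g, lower = pf$mean - 5 * pf$sd,
                          upper = pf$mean + 5 * pf$sd, tol = 1e-10)
    params$numeric[[f]]$mu <- sol$root
  }

  mc <- with_seed(params$calibration$seed, {
    feats <- sample_features(params, params$calibration$n_mc)
    noise <- stats::rnorm(params$calibration$n_mc, 0, params$time_model$noise_sd)
    u_lab <- stats::runif(params$calibration$n_mc)
    list(feats = feats, noise = noise, u_lab = u_lab)
  })

  # 2. risk intercept
  rm <- params$risk_model
  eta0 <- risk_eta0(mc$feats, rm)
  if (is.na(rm$intercept)) {
    f_prev <- function(b0) mean(stats::plogis(b0 + eta0)) - rm$prevalence
    params$risk_model$intercept <-
      stats::uniroot(f_prev, lower = -25, upper = 10, tol = 1e-9)$root
  }
  prob <- stats::plogis(params$risk_model$intercept + eta0)
  label <- as.integer(mc$u_lab < prob)

  # 3. time baseline and effect scale (fixed point on the clipped moments)
  tm <- params$time_model
  terms <- time_terms(mc$feats, label, tm)
  if (is.na(tm$scale) || is.na(tm$baseline)) {
    s <- 1
    baseline <- 0
    for (iter in 1:40) {
      f_mean <- function(b) {
        mean(clamp(b + s * terms + mc$noise, tm$low, tm$high)) - tm$target_mean
      }
      baseline <- stats::uniroot(f_mean, lower = -200, upper = 200,
                                 tol = 1e-8)$root
      realized_sd <- stats::sd(clamp(baseline + s * terms + mc$noise,
                                     tm$low, tm$high))
      ratio <- tm$target_sd / realized_sd
      if (abs(ratio - 1) < 1e-4) break
      s <- s * ratio
    }
    params$time_model$scale <- s
    params$time_model$baseline <- baseline
  }
  params$calibrated <- TRUE
  params
}

#' Assign complication labels and surgery times
#'
#' Applies the ground-truth outcome model to a table of features: a
#' Bernoulli complication label through a logistic risk score, then a
#' surgery time equal to `baseline + scale * (effect terms) + noise`,
#' clipped to the configured range. Uses the current RNG state.
#'
#' @param features data.frame holding at least `kind_of_surgeon`,
#'   `axial_length` and `iol_power`.
#' @param params a calibrated `generator_params`.
#' @return list with `complication` (integer 0/1), `surgery_time` (minutes),
#'   `probability` (the logistic risk used for each record) and
#'   `expected_time` (the noise-free, pre-clipping model time).
#' @export
assign_outcomes <- function(features, params) {
  stopifnot(inherits(params, "generator_params"))
  if (!isTRUE(params$calibrated) &&
      (is.na(params$risk_model$intercept) || is.na(params$time_model$baseline)))
    stop("params not calibrated; call calibrate_generator() first")
  n <- nrow(features)
  rm <- params$risk_model
  tm <- params$time_model
  prob <- stats::plogis(rm$intercept + risk_eta0(features, rm))
  label <- stats::rbinom(n, 1L, prob)
  expected <- tm$baseline + tm$scale * time_terms(features, label, tm)
  time <- clamp(expected + stats::rnorm(n, 0, tm$noise_sd), tm$low, tm$high)
  list(complication = as.integer(label), surgery_time = time,
       probability = prob, expected_time = expected)
}

#' Generate a synthetic cohort
#'
#' Draws `n` patient records under `params` and the ground-truth outcome
#' model, deterministically for a fixed seed.
#'
#' @param params a `generator_params`; defaults to the calibrated
#'   population-table parameters.
#' @param seed integer seed (required: cohorts are reproducible artifacts).
#' @param n cohort size; defaults to `params$n`.
#' @return A `cohort_table` with an additional `"risk_probability"`
#'   attribute (the per-record ground-truth complication probability).
#' @export
generate_cohort <- function(params = default_generator_params(), seed,
                            n = params$n) {
  if (missing(seed)) stop("seed is required")
  if (!is_count(n)) stop("parameter error: n must be a positive integer")
  if (!isTRUE(params$calibrated)) params <- calibrate_generator(params)
  out <- with_seed(seed, {
    feats <- sample_features(params, n)
    oc <- assign_outcomes(feats, params)
    list(feats = feats, oc = oc)
  })
  df <- out$feats
  df$surgery_time <- out$oc$surgery_time
  df$id <- sprintf("S%07d", seq_len(n))
  df$complication <- out$oc$complication
  tab <- as_cohort_table(df, strict = TRUE)
  attr(tab, "risk_probability") <- out$oc$probability
  attr(tab, "seed") <- as.integer(seed)
  tab
}
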