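# phacorisk

Tools for studying intraoperative complication risk in phacoemulsification
cataract surgery from patient-level tabular data, and for predicting how
long a procedure will take.

## The problem

Cataract surgery complications (capsular tears with or without vitrectomy,
iris prolapse, nucleus drop, ...) are rare — typically a few percent of
procedures — and teaching hospitals want to know which preoperative
features flag risky cases, especially when residents operate. Two analysis
questions drive this package:

1. **Which feature subsets separate complicated from uncomplicated
   cases?** Every non-empty subset of 22 clinical features (age, sex, eye,
   systemic and ocular disease, cataract type, BCVA, refraction, IOP, IOL
   power, axial length, keratometry, ACD, endothelial cell count,
   anesthesia, surgery time, extra device, kind of surgeon — 2²² − 1 =
   4,194,303 subsets) is evaluated with a Gaussian discriminant classifier
   under **balanced undersampling**: because complications are a small
   minority (prevalence ~6%), each of R randomizations keeps all m
   complication records plus m uniformly drawn controls, splits the
   balanced set 2/3 train / 1/3 test (stratified), and scores accuracy
   (ACC), specificity (SPC) and sensitivity (TPR) in percent. Subsets are
   ranked by mean ACC and a feature's importance is its **occurrence
   count**: the number of subsets with mean ACC > τ (default τ = 72%) that
   contain it.
2. **Can surgery time be predicted preoperatively?** A feedforward network
   with 21 input neurons (all features except surgery time; non-members of
   a candidate configuration are zeroed), 10 sigmoid hidden neurons and a
   linear output is trained by full-batch backpropagation (damped
   Gauss-Newton by default) on a 2/3–1/3 split, and configurations are
   compared by the maximum absolute test error in minutes.

Five discriminant variants are implemented from their density formulas —
`linear` (pooled covariance), `diaglinear` (pooled per-feature variances),
`quadratic` / `diagquadratic` (per-class), and `mahalanobis` (per-class
distance rule, no priors): class c scores
`log π_c − ½ log|Σ_c| − ½ (x−μ_c)ᵀ Σ_c⁻¹ (x−μ_c)`, ties to the lower
class.

Because no clinical cohort is publicly deposited, the package ships a
**calibrated synthetic-cohort generator**: truncated-normal numeric
marginals and categorical frequencies matching the published population
tables of a 1,229-eye teaching-hospital cohort, a logistic ground-truth
risk model on surgeon type and on axial-length / IOL-power deviation
(calibrated to 73/1,229 complications, stratified 48 trained / 25
resident), and an additive surgery-time model whose realised marginal is
calibrated to 17.58 ± 9.42 min on [5, 85]. Every pipeline stage is
therefore testable end to end; see `vignettes/phacorisk-methods.Rmd` for
what the generator does and does not emulate.

## Worked example

```r
library(phacorisk)

cohort <- generate_cohort(seed = 1)          # calibrated synthetic cohort
nrow(cohort); sum(cohort$complication)
#> 1229 records, 68 complications
mean(cohort$surgery_time); sd(cohort$surgery_time)
#> surgery time 17.66 +/- 9.39 min

fm <- encode_features(cohort)                # ordinal-coded 1229 x 22 matrix
s  <- evaluate_subset(fm$X, fm$y,
                      c("kind_of_surgeon", "axial_length", "iol_power"),
                      classifier_spec("discriminant", "diaglinear"),
                      R = 100, seed = 2)
print(s)
#> Balanced evaluation (discriminant:diaglinear), R = 100
#>   subset [3]: iol_power + axial_length + kind_of_surgeon
#>   ACC 54.5 +/- 6.8  SPC 64.7 +/- 16.6  TPR 44.4 +/- 14.0
```

The mean ACC of 54.5% is the honest answer for this subset in the default
synthetic world: the generator's risk effects on axial length and IOL
power are two-sided deviations from the population centre, which a
linear-boundary diaglinear rule cannot exploit, and the surgeon effect is
calibrated to the modest published stratification. The ±6.8 is the SD over
the 100 balanced randomizations, dominated by which controls were drawn.

Surgery time, in contrast, is strongly predictable from its true drivers:

```r
Xin  <- fm$X[, setdiff(colnames(fm$X), "surgery_time")]
scan <- scan_configurations(Xin, cohort$surgery_time,
          feature_subset(c("iol_power", "axial_length", "kind_of_surgeon")),
          network_spec(), seed = 3, strata = fm$y)
scan[, c("features", "max_abs_error", "rmse")]
#>                                  features max_abs_error     rmse
#> 1 iol_power+axial_length+kind_of_surgeon      6.273232 1.448793
```

A test-set RMSE of 1.45 min sits at the generator's irreducible noise
floor (≈1.40 min); the maximum absolute error of ~6 min is set by the rare
worst-case record in the held-out third.

An exhaustive search over a feature pool, with ranked indicator tables and
occurrence counts, plus a single-command pipeline
(`generate → search → predict-time → report`):

```r
res <- search_subsets(fm$X, fm$y,
         search_config(features = c("kind_of_surgeon", "axial_length",
                                    "iol_power", "age", "sex"),
                       R = 50, threshold = 72, seed = 4))
top_results(res, 10); occurrence_counts(res, 72)

run_pipeline(run_config(seed = 1, out_dir = "phacorisk_run"))
```

A command-line wrapper lives at `inst/cli/phacorisk.R`
(`generate` / `search` / `predict-time` / `demo` subcommands).

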