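---
title: "phacorisk: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phacorisk: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models it
implements, the synthetic world it calibrates, the numerical choices made
where the design was genuinely open, and the limits of what a green test
establishes. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline

Patient-level records carry 22 clinical features in a fixed canonical
order, a binary intraoperative-complication label, and an id
(`cohort_schema()`). The analysis stages are:

1. **Encoding** (`encode_features()`): numerics pass through; categoricals
   become integer codes in *sorted level order* (deterministic and
   spec-independent), or one-hot indicators on request. One column per
   feature mirrors the way feature subsets are defined.
2. **Balanced evaluation** (`evaluate_subset()`): complications are ~6% of
   records, so each randomization undersamples the majority to the
   minority size m (all m cases + m uniform controls), splits the balanced
   set stratified 2/3 train / 1/3 test, fits a classifier, and scores
   ACC / SPC / TPR in percent. Means and SDs over R randomizations
   summarise one (subset, classifier) pair. On an exactly balanced test
   set, ACC = (TPR + SPC)/2 holds identically — asserted per
   randomization in the tests.
3. **Exhaustive search** (`search_subsets()`): every non-empty subset of a
   feature pool, in ascending-bitmask order. 22 features give
   2²² − 1 = 4,194,303 subsets; desk-scale runs restrict the pool or cap
   the subset size, and the count is also available in closed form
   (`count_subsets()`). Ranking is by mean ACC, ties to the smaller
   subset, then lower bitmask (the tie rules are our choice; nothing in
   the source material fixes them). Feature importance is the
   **occurrence count**: the number of subsets with mean ACC strictly
   above τ (default 72%) containing the feature.
4. **Surgery-time prediction** (`fit_time_network()`,
   `scan_configurations()`): a 21-input, 10-hidden-sigmoid, linear-output
   network predicts surgery time in minutes; candidate configurations
   zero the non-member inputs so the architecture never changes.
5. **Reporting** (`run_pipeline()`): stages wired into a run directory,
   every artifact stamped with a config fingerprint and the master seed;
   reruns of deterministic stages are byte-identical.

### Reproducible randomness

Every unit of work owns an RNG stream derived as
`derive_seed(master, subset_mask, randomization_index)` (a mixed-modular
map onto 31-bit seeds). Consequences: chunked or parallel execution of a
search is exactly identical to serial execution, and a failed
randomization can be redrawn (bounded retries) without disturbing any
other stream.

## 2. The synthetic cohort: a stated world

No clinical dataset is deposited, so the generator
(`generator_params()`, `generate_cohort()`) *states* a world with the
published population structure and known ground truth. It emulates:

- **Numeric marginals** as truncated normals with the published mean, SD
  and range (age 70.2 ± 10.3 on [10, 94], axial length 23.89 ± 2.08 on
  [17, 35.82], IOL power 20.15 ± 5.59 on [−7, 34], ...). Sampling is by
  inverse CDF, and the underlying location is solved per feature so the
  *truncated* mean equals the target (asymmetric truncation would
  otherwise bias features like BCVA by ~0.03).
- **Derived optics**: spherical equivalent is its clinical identity
  SE = sphere + cylinder/2 (mean −1.45 D follows exactly from the sphere
  and cylinder targets); keratometry meridians are
  mean K ∓ astigmatism/2 with a half-normal corneal astigmatism (SD 1 D,
  capped at 6 D — our choice; the source tabulates only mean K).
- **Categorical frequencies** renormalised from the published *counts*
  (counts are primary data; some printed percentages and totals are
  internally inconsistent, e.g. the procedure counts sum to 1,224 and the
  anesthesia percentages do not match their counts). The cataract-type
  level printed as "Total 62 (5%)" is kept as the clinical category
  *total cataract* without further interpretation. Extra-device
  frequencies are not tabulated anywhere; the defaults (none 92%, iris
  hooks 3%, Malyugin ring 2.5%, trypan blue 2.5%) are our choice, and the
  feature is deliberately independent of outcome.
- **Complication risk**: logistic in surgeon type (resident log-odds 1.2,
  matching the published stratification of 48 trained / 25 resident
  complications at 181/1,224 resident procedures) and in the *absolute
  deviations* |AL − 23.89| (0.12/mm) and |IOL − 20.15| (0.05/D) — a
  wide-range, two-sided effect, reflecting the reported finding that the
  implicated AL / IOL values spanned the whole range rather than one
  tail. The intercept is solved on a fixed-seed Monte Carlo sample so the
  expected count at n = 1,229 is 73.
- **Surgery time**: baseline + scale × (15 min resident + 3 min
  complication + 4 min/mm |AL dev| + 1.71 min/D |IOL dev|) + N(0, 1.2 min),
  clipped to [5, 85]. Baseline and scale are solved so the realised
  clipped marginal matches 17.58 ± 9.42 min.

An optional Gaussian-copula association between AL and IOL power is
available (`al_iol_correlation`) but **off by default**: the source gives
only marginals, and we do not invent joint structure silently. Note the
consequence: independent sampling produces clinically impossible eyes
(short AL with high-for-long-eyes IOL power), which become high-leverage
records in the time model (Section 5).

### Why noise SD 1.2 min and a 3-minute complication increment

The time-model defaults were chosen *a priori* from one constraint: a
well-fit predictor evaluated on a held-out third (~410 records) should be
able to land in the reported "maximum error below ~6 minutes" regime. The
expected maximum of n absolute Gaussian residuals is ≈ σ·√(2 ln 2n) — 3.5σ
at n = 410. A 4-minute noise SD would therefore put the *best possible*
max error near 14 minutes; reaching the 6-minute regime requires the
unpredictable component (noise + complication surprise) to stay below
~1.7 min SD. Hence σ = 1.2 min and a +3 min direct complication increment,
with the large published marginal SD (9.42 min) carried instead by the
*predictable* terms (resident, |AL dev|, |IOL dev|). The cost of this
choice is documented, not hidden: complications lengthen surgery only
weakly and directly (+3 min) in this world — far less than a real
vitrectomy does — although complicated cases still run longer on average
through the shared drivers. These are tunables (`time_model`), not claims
about clinical data.

### What a green test does and does not establish

Green calibration tests establish that the generator reproduces the
*stated marginals, counts and stratification* and that the pipeline's
machinery (classifiers, evaluation, search, network) is correct against
independent oracles. They establish nothing about the real cohort's joint
distribution, about the published classifier accuracies (ACC ≈ 87% with
surgery time as input), or about occurrence counts of the real data —
those were computed on an undeposited dataset, and this package does not
attempt to reproduce them.

In particular, in the *default* world the true risk trio
{kind of surgeon, axial length, IOL power} yields balanced diaglinear
accuracies in the mid-50s: the two-sided |AL dev| / |IOL dev| effects move
class *variances*, not means, and are invisible to a linear boundary; the
surgeon effect calibrated to 48/25 is modest. This is the honest Bayes-level
consequence of the stated risk model, not an implementation deficiency.
Signal-recovery tests therefore use a **planted-signal configuration**:
risk centres moved to the feature range minima (so the deviations are
monotone and linearly learnable) with strong coefficients (surgeon 3.0,
AL 0.5/mm, IOL 0.2/D), prevalence recalibrated to 73/1,229. Under that
world, subsets containing planted features clear τ = 72% with margin and
the three planted features hold the top occurrence counts.

## 3. Discriminant classifiers

All five variants share per-class means and empirical priors and differ in
covariance structure: pooled full (`linear`), pooled diagonal
(`diaglinear`), per-class full (`quadratic`), per-class diagonal
(`diagquadratic`). Density variants assign
argmax of log π_c − ½ log|Σ_c| − ½ (x−μ_c)ᵀ Σ_c⁻¹ (x−μ_c); the
`mahalanobis` variant is the conventional distance-only rule (per-class
covariance, no prior or determinant terms) — a convention we document
because the source does not define it. Numerical choices:

- ridge ε = 10⁻⁶ × mean pooled per-feature variance (floored at 10⁻¹²) on
  every stored variance/diagonal; escalated tenfold with a message if a
  full covariance is still not positive definite (constant features,
  duplicated records);
- Cholesky-based quadratic forms, no explicit inverses;
- ties break deterministically to the lower class index;
- `posterior()` is the softmax of the joint log scores and is refused for
  the mahalanobis variant, whose scores are not calibrated densities.

Gaussian naive Bayes is *exactly* the diagquadratic rule, so
`classifier_spec("naive_bayes")` maps onto it. Other bake-off families
(neural network, decision tree, SVM) are accepted through the
`fit`/`predict` plug-in interface; no backend for them ships with the
package's declared dependencies.

## 4. Evaluation and search defaults

- Positive class = complication, so TPR is sensitivity to complications.
- Holdout fraction 1/3 (the only split the source states, for the time
  predictor) with per-class rounding, so a balanced input gives a
  balanced test set.
- R defaults to 1,000 (family bake-off) and 6,000 (variant comparison) in
  the published protocol; desk-scale runs and the tests use R = 20–200.
  SDs reported are across-randomization SDs.
- Threshold τ is strict (`ACC > τ`), per the published table caption.
- A subset whose every randomization fails is recorded `failed = TRUE`,
  excluded from ranking and occurrence counts, never silently dropped.

## 5. The surgery-time network

Architecture is fixed (21 sigmoid-hidden-10 linear); training
hyperparameters are not specified anywhere, so they are our choice and are
config-exposed (`network_spec()`). Two full-batch trainers:

- **`lm`** (default): damped Gauss-Newton (Levenberg-Marquardt) on the
  standardized problem — the standard trainer for small feedforward
  regression networks. Deterministic given the init seed; converges to the
  noise floor on the default world within ~200 iterations.
- **`gd`**: plain backpropagation with classical momentum. Kept as the
  reference first-order method; on the default world it needs thousands of
  epochs and shows large init-to-init spread at high-leverage records,
  which is why it is not the default.

Inputs and target are standardized internally (constant columns get unit
scale); predictions are mapped back to minutes. Configurations zero
non-member inputs, whose Jacobian columns vanish — the damping makes the
normal equations well-posed regardless. Training aborts on non-finite
loss, and a final-worse-than-initial loss is treated as divergence.

**Known limitation (leverage corners).** With independent AL and IOL
marginals, a default cohort contains a few records extreme in two or three
drivers at once (model times 50+ minutes, 4 SDs above the mean). When such
a record falls in the held-out third, its neighbourhood may be empty in
training and the network under-predicts it by several minutes — the
per-run maximum absolute error is then set by that single record. The mean
max error over repeated splits consequently hovers around the 6-minute
regime boundary rather than safely below it; the acceptance suite reports
this number as computed. The test RMSE, in contrast, sits at the
irreducible floor √(σ² + complication-term variance), which is the
parameter-recovery property the tests assert (within 25% of σ).

`compare_times()` reports the paired Student t on predicted-minus-actual
differences, their MSE, and a Kolmogorov-Smirnov normality *flag* (the KS
p-value uses sample moments, hence is approximate — it gates nothing).
Zero-variance differences yield a flagged NA, never a fabricated 0.

## 6. Degenerate inputs and edge rules

- Truncated-normal sampling requires `low < high`, `sd > 0`; an interval
  of near-zero width is legal and returns its endpoints.
- `balanced_sample()` needs m ≥ 2 minority records; evaluation errors
  otherwise.
- Zero-denominator metrics (no positives or no negatives in a test set)
  are NA + `degenerate` flag.
- Cohort CSVs are written with 17 significant digits, so
  read(write(x)) round-trips bit-identically.
- Strict validation rejects any out-of-range numeric, unknown level,
  missing value or duplicated id; permissive mode flags rows in a
  validation report and imputes (median / mode).

## 7. Summary of open choices made

| Choice | Value | Why |
|---|---|---|
| categorical encoding | ordinal, sorted levels | one column per feature, as subsets require |
| missingness | reject (strict) / impute median-mode (permissive) | source never mentions missingness |
| time-model noise SD | 1.2 min | max-error-regime constraint (Section 2) |
| complication increment | +3 min | same constraint; documented cost |
| risk shape | two-sided \|dev\| terms | wide-range finding; see Section 2 |
| mahalanobis rule | per-class Σ, no priors/log-dets | conventional definition |
| tie-breaks | lower class; smaller subset, lower mask | determinism |
| τ threshold | strict > | caption wording |
| trainer | LM default, GD option | convergence quality (Section 5) |
| AL-IOL correlation | hook, off by default | don't invent joint structure |
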