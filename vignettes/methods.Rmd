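---
title: "Radiomic knee scores and final-height prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic knee scores and final-height prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radheight)
```

## The prediction problem

After menarche a girl grows for roughly two more years, typically gaining
5–9 cm. Whether to intervene on height has to be decided inside that window,
so an accurate prediction of *final* height from data available *at menarche*
matters clinically. The classical tools are

* **bone-age projection**: divide the current height by the tabulated
  percentage of mature height attained at the child's bone age (BA), read
  from a hand-wrist (Greulich–Pyle, GP) or knee (Pyle–Hoerr, PH) atlas; and
* **target height**: the sex-adjusted mid-parental height,
  `(father + mother)/2 − 6.5` cm for girls.

Both are noisy: atlas reading is subjective, and mid-parental height ignores
the child entirely. This package implements a combined approach — a
*radiomic score* of the knee epiphyses, built from texture features of a
plain radiograph, entered alongside clinical covariates into a stepwise OLS
prediction equation — together with the evaluation battery needed to compare
all of these methods on equal terms.

## Radiomic features

Regions of interest (distal femoral and proximal tibial epiphyses) are
delineated as polygons in labelme-style JSON and rasterized with a
pixel-center even-odd rule (0-based coordinates, x = column, y = row; a
pixel's center sits at integer coordinates). Features are computed on the
original image and on two wavelet bands, giving per ROI:

* **first-order** statistics of the raw intensities (mean, median, minimum,
  maximum, range, N-denominator variance, 10th/90th percentile and IQR with
  linear interpolation, robust mean absolute deviation over the 10–90
  percentile core);
* **shape** descriptors of the mask under the original filter only (major and
  minor axis from the sample covariance of pixel centers, maximum boundary
  diameter, crack-edge perimeter, pixel count);
* **texture matrices** on intensities discretized to a fixed bin width
  (default 25 intensity units, the customary default for 8-bit exports):
  GLCM, GLRLM, GLSZM, GLDM, NGTDM.

Conventions, chosen once and applied everywhere: 4 planar directions at
distance 1 with symmetric GLCMs and per-direction averaging; 8-connected
zones and dependences; GLDM dependence tolerance α = 0 with the dependence
index stored as count + 1; NGTDM statistics over pixels with at least one
in-mask neighbor. The default configuration yields 113 features per ROI; the
exact key set is a pure function of the configuration and is hashed into
every output.

The **wavelet filter** is a single-level *stationary* (undecimated) separable
2D transform with a Coiflet-1 kernel and periodic boundaries: band L
low-passes both axes, band H high-passes both axes. Because no downsampling
occurs, the output has the input's shape and the ROI mask applies unchanged.
Filters are normalized to unit DC gain, so L preserves a constant image
exactly and H annihilates it. Two-band naming (L/H) aggregates the four
possible separable sub-bands into the two extremes; the mixed sub-bands
(LH/HL) are deliberately not computed.

Everything is computed in pixel units — radiograph exports typically discard
physical spacing, and all downstream uses are scale-consistent within a
cohort.

## Feature reduction and the radiomic score

Four stages, each shrinking (never reshuffling) the feature set:

1. **Reliability gate.** Features are re-extracted from a second observer's
   delineations (inter-observer subset) and from a repeat session of the
   first observer (intra-observer subset). A feature passes iff its
   inter-observer ICC(2,1) (two-way random effects, absolute agreement — a
   systematic delineation bias should count against a feature) *and* its
   intra-observer ICC(3,1) (consistency) both exceed 0.8.
2. **Variance threshold.** Features with sample variance ≤ 0.8 are dropped.
   The variance is measured on *raw* values by default: min-max scaling
   bounds the variance by 0.25 (a 0.8 threshold would remove everything) and
   z-scoring forces every variance to 1 (it would remove nothing), so
   neither normalization yields a meaningful 0.8 rule. Both remain
   selectable for sensitivity analyses and the choice is recorded in the
   output.
3. **Univariate screen.** Per-feature F-test of the simple regression on
   final height (identical to the squared slope t); keep P < 0.05.
4. **LASSO.** L1-penalized regression on standardized survivors, penalty by
   10-fold cross-validation (minimum-MSE rule by default, 1-SE by flag)
   under a fixed seed. The non-zero terms and intercept define the score's
   linear form `S`, with the training means/SDs stored so the score can be
   applied to new subjects without leaking test-set information.

The reported radiomic score is `sign(S)·log(|S|)` (natural log): odd in `S`,
zero at `|S| = 1`. Because the transform diverges as `S → 0`, scores with
`|S| ≤ 1e−8` raise an error rather than being clamped — silent clamping
would hide a degenerate signature. The package also ships a published
reference signature for both sites as a coefficient CSV (applied to raw
feature values — the source publishes no standardization block; both sites
carry the same printed intercept, 160.0959, which may be a typographical
artifact of the source table and is shipped as printed).

## Prediction equations

`stepwise_select()` builds the OLS equation from seven candidates: father's
and mother's height, height at menarche, mean GP and PH bone age, and the
femur and tibia scores. Starting from the constant model, each iteration
trials the candidate most strongly correlated with the current residuals and
accepts it iff the nested (extra-sum-of-squares) F-test of the extended
model has P < 0.05 *and* the entering variable's t-test has P < 0.10 (for a
single added variable the two P values coincide, so the entry threshold
binds). A rejected candidate is excluded from further candidacy and the
search continues; entered variables are never removed. Reported per
equation: coefficients with 95% CIs, t and P, partial correlations through
the identity `|r| = |t|/√(t² + df)`, R², adjusted R², overall F, and
AIC/BIC under the Gaussian profile likelihood with the parameter count
including intercept and error variance — comparable only within this
convention, which is why the manifest records it.

Model comparisons use the nested F-test and the likelihood-ratio deviance
`D = n·ln(SSE_r/SSE_f)` on a χ² with the added-parameter degrees of freedom.
Robustness is checked by Huber IRLS regression (tuning 1.345) against the
OLS coefficients.

## Evaluation

All methods are scored on residuals oriented `final − predicted`:

* RMSE and `R² = 1 − SSE/SST` with `SST = Σ(final − mean)²` — the raw sum
  of squares, which makes `R² = 1 − n·RMSE²/SST` an exact identity and can
  go negative for methods worse than the cohort mean;
* RPD = sample SD (n − 1) of final heights divided by RMSE;
* residual buckets `|res| ≤ 2`, `2 < |res| < 5`, `≥ 5` cm — boundaries fall
  in the outer buckets;
* Bland–Altman bias and 95% limits of agreement `mean ± 1.96·SD` (sample
  SD), same orientation as the residuals;
* a paired t-test of predicted vs observed means (two-sample variant by
  flag).

The OLS equations are evaluated out-of-fold under a seeded 5-fold plan with
fold sizes differing by at most one: the predictor set stays fixed (selection
is run once on the full sample, matching the study design this emulates),
while coefficients are refitted per training fold; out-of-fold predictions
are pooled before metrics are computed. Re-running selection inside each
fold is available by passing a function recipe to `kfold_predict()`.

## The synthetic cohort generator

No patient data ship with the package; `generate_clinical()` and
`generate_cohort()` produce cohorts that emulate the study conditions: the
clinical marginals (height at menarche 150.62 ± 4.28 cm, father 172.34 ±
5.46, mother 159.10 ± 5.30, GP bone age 12.35 ± 0.79 y, PH 12.76 ± 0.58 y,
final height 159.56 ± 3.81 cm), a linear generative link with residual SD
2.0 cm, and procedural epiphysis images.

Two independent standard-normal latents drive each subject:

* **skeletal maturity** feeds both atlases' bone ages (GP = 0.45·z(age) +
  0.55·maturity + reader noise of SD 0.25 y; PH with loadings 0.30/0.25, an
  atlas-specific component of SD 0.39, and ±0.15 y systematic reader
  offsets). It lowers final height only through the bone-age coefficient —
  an advanced bone age at menarche means less remaining growth.
* **growth reserve** `m` is what the femur texture encodes; it raises final
  height directly. Collapsing the two into one latent would make bone age's
  marginal correlation with final height nearly vanish (its negative direct
  path and the positive maturity path cancel), contradicting the empirical
  pattern that bone age correlates negatively and the femur score positively
  with final height; the two-latent structure reproduces both signs.

Generative coefficients default to height at menarche 0.70, father 0.15,
GP bone age −1.91, growth reserve 0.80 (sign pattern of the combined
equation; magnitudes set by a variance budget keeping the final-height SD
within 10% of its target and by a power analysis making every true
predictor detectable at n = 173 with 2 cm residuals). The femur score is a
noisy affine transform of `m` with noise SD 0.25, calibrated so its marginal
R² with final height is ≈ 0.19; the tibia score is pure noise, emulating a
null imaging site. Correlations among the anthropometric variables default
to 0.2–0.4 (only marginals are published; these are plausible
family-stature values).

Rendered images are 256×256 texture phantoms: an elliptical epiphysis and a
metaphysis separated by a physis band that narrows with maturity, speckle
whose contrast grows with `m × texture_effect`, and Gaussian noise. The true
ROI is a 24-vertex ellipse polygon; simulated observers jitter each vertex
by Gaussian displacements (rejecting self-intersections). The phantom is
*not* anatomically realistic: passing tests show that the pipeline recovers
a planted texture→height signal through delineation jitter, discretization
and wavelet filtering — they do not show that real epiphyseal texture
carries such a signal, which is exactly the substantive claim that needs
clinical data.

## Numerical choices and problem sizes

* Discretization bin width 25 (configurable); intensity-shift invariance is
  guaranteed by anchoring bins at the observed minimum.
* Degenerate texture directions (a thin ROI with no pixel pairs) fall back
  to a one-cell matrix rather than NaN.
* `cv.glmnet` convergence threshold is left at its default; the λ = 0 path
  is solved at `thresh = 1e−12` when used as a least-squares check.
* Huber IRLS: tolerance 1e−8, 200 iterations, error on non-convergence.
* All randomness flows from one master seed through stage-name-keyed
  substreams, so toggling one stage never perturbs another's draws; every
  run directory carries a manifest with the config hash and output
  checksums, and re-running a manifest reproduces outputs bit for bit.
* Simulation sizes: stepwise recovery and method comparison use 50
  replicate cohorts of n = 173 at the clinical level; the imaging chain is
  exercised end-to-end on smaller cohorts (n = 20–30, 96–128 px images) and
  its texture-monotonicity property on 50 rendered ROIs. These sizes give
  stable Monte-Carlo estimates of the quantities asserted while keeping the
  default build reproducible in minutes.

## Known limitations

* The shipped percentage-of-mature-height table is a **synthetic** stand-in
  (monotone, 8–17 y) calibrated to the systematic overprediction reported
  for hand-wrist projections in this population; it is not the published
  projection table, and absolute BP predictions from it should not be used
  clinically.
* The reference score signature is applied to raw feature values; if the
  original features were standardized before the printed coefficients were
  fit, scores computed here differ by an affine change per feature.
* Forward-only selection cannot undo an early entry that later predictors
  render redundant.
* 2D features only; no Laplacian-of-Gaussian or mixed wavelet sub-bands; no
  cross-scanner harmonization.

## A worked run

```{r, eval = FALSE}
dir <- tempfile()
generate_cohort(generator_config(n_subjects = 30, seed = 95,
                                 image_size = 96), file.path(dir, "cohort"))
rc <- run_config(file.path(dir, "cohort"), file.path(dir, "out"), seed = 7)
res <- run_pipeline(rc)
res$stepwise$fit       # the selected equation
res$comparison$table   # RMSE / R2 / RPD / buckets / Bland-Altman per method
```
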