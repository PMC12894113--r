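# radheight

Predicting the adult height of girls at menarche from knee radiographs and
clinical covariates.

Menarche opens the last ~2-year window in which height can still be
influenced, so clinicians need an accurate prediction of final height from
data available at that visit. The classical tools — bone-age (BA) projection
(current height divided by the tabulated percentage of mature height
attained at the child's bone age) and sex-adjusted mid-parental *target
height* `(father + mother)/2 − 6.5` cm — are subjective or ignore the child
entirely. `radheight` implements a combined alternative and the machinery
to evaluate it:

1. **2D radiomics** of the distal femoral and proximal tibial epiphyses:
   first-order, shape, GLCM, GLRLM, GLSZM, GLDM and NGTDM features under the
   original and wavelet-filtered (stationary Coiflet-1, L/H bands) images,
   from polygon annotations rasterized by a pixel-center even-odd rule.
2. **A feature-reduction cascade**: inter-observer ICC(2,1) and
   intra-observer ICC(3,1) reliability gate (both > 0.8) → variance
   threshold (> 0.8) → univariate F-screen (P < 0.05) → LASSO with
   cross-validated penalty, yielding a per-site **radiomic score**
   `sign(S)·log|S|`, where `S` is the selected linear combination.
3. **Stepwise OLS height equations** over seven candidates (parental
   heights, height at menarche, GP and PH bone age, femur/tibia scores)
   with nested-F entry (P < 0.05) and variable retention (P < 0.10),
   reporting coefficients with CIs, partial correlations
   (`|r| = |t|/√(t²+df)`), R², adjusted R², F, AIC, BIC, plus
   likelihood-ratio comparisons and a Huber-regression robustness check.
4. **Evaluation** under seeded 5-fold cross-validation: RMSE,
   `R² = 1 − SSE/SST`, RPD (SD of final height / RMSE), residual buckets
   (≤ 2, 2–5, ≥ 5 cm), Bland–Altman bias and 95% limits of agreement, and
   paired t-tests — for the OLS equations, GP-BP and PH-BP projections, and
   target height side by side.
5. **A synthetic-cohort generator** (clinical tables with realistic
   marginals plus procedural epiphysis-texture phantoms and simulated
   observer jitter), so the entire pipeline is testable without any patient
   data.

## Worked example

```r
library(radheight)

coh  <- generate_clinical(generator_config(n_subjects = 173, seed = 7))
cand <- height_candidates(coh$clinical, coh$truth$femur_score,
                          coh$truth$tibia_score)
sw   <- stepwise_select(cand, coh$clinical$final_height)
sw$fit
#> OLS equation (n = 173)
#> Term                              Estimate (95% CI)          t (P)      Partial r (P)
#> (Intercept)                    42.043 ( 28.479,  55.606)    6.12 (0.00)          -
#> height_menarche                 0.664 (  0.582,   0.746)   16.07 (0.00)  0.78 (0.00)
#> ba_gp_mean                     -1.832 ( -2.214,  -1.450)   -9.46 (0.00) -0.59 (0.00)
#> father_height                   0.183 (  0.122,   0.244)    5.95 (0.00)  0.42 (0.00)
#> femur_score                     1.658 (  1.052,   2.263)    5.41 (0.00)  0.38 (0.00)
#> R2 0.759 | adj R2 0.753 | F 132.4 (P 7.43e-51) | AIC 721.9 | BIC 740.8
```

The selected equation combines height at menarche (+0.66 cm per cm), GP
bone age (−1.83 cm per year of skeletal advancement — more mature girls
have less growth left), father's height and the femur radiomic score; the
tibia score and mother's height do not enter. Comparing methods under
5-fold cross-validation:

```r
df <- coh$clinical
df$femur_score <- coh$truth$femur_score
compare_methods(df, plan = cv_plan(173, 5, seed = 7))$table
#>          method rmse     r2   rpd pct_le2  ba_bias loa_low loa_high
#>         ols_eq1 1.96  0.739 1.963    69.4 -0.01249   -3.87     3.84
#>         ols_eq2 2.08  0.706 1.849    64.7  0.00366   -4.09     4.10
#>         ols_eq3 2.42  0.603 1.592    59.0 -0.01529   -4.77     4.74
#>           gp_bp 4.49 -0.367 0.858    27.7 -3.44828   -9.09     2.19
#>           ph_bp 3.61  0.115 1.066    38.7 -1.86680   -7.94     4.21
#>   target_height 4.35 -0.288 0.884    35.8 -0.51159   -9.01     7.99
```

The full equation (`ols_eq1`) predicts final height to ~2 cm RMSE with
negligible bias and ±3.9 cm limits of agreement; dropping the radiomic
score (`ols_eq2`) or the bone age (`ols_eq3`) costs accuracy, and the
traditional projections trail far behind (negative R² means worse than
predicting the cohort mean; the negative `ba_bias` of `gp_bp` is its
systematic overprediction). Residuals are oriented `final − predicted`
throughout.

The imaging half of the pipeline — PNG images + labelme-style annotations →
masks → features → reliability gate → cascade → scores → equations →
evaluation, with every intermediate table and a reproducibility manifest
written to disk — runs via `generate_cohort()` + `run_pipeline()`; see the
methods vignette (`vignettes/methods.Rmd`) and the thin CLI wrappers in
`inst/scripts/`.

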