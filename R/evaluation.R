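#' Five-fold cross-validation plan
#'
#' Seeded random partition of `n` subjects into `k` folds whose sizes differ
#' by at most one.
#'
#' @param n number of subjects.
#' @param k number of folds (default 5).
#' @param seed integer seed for the assignment draw.
#' @return List of class `cv_plan` with `k`, `seed`, and the integer `fold`
#'   assignment per subject.
#' @export
cv_plan <- function(n, k = 5, seed = 1) {
  if (k < 2 || k > n) stop("k must lie in [2, n]", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  structure(list(k = k, seed = seed, fold = fold), class = "cv_plan")
}

#' Out-of-fold predictions for a fixed model recipe
#'
#' For each fold, the model is refitted on the other folds (coefficients —
#' and, when the recipe involves any, standardizations — are re-estimated on
#' the training folds only) and predictions are produced for the held-out
#' subjects. The predictor set itself is fixed across folds, matching the
#' design in which variable selection is run once on the full sample;
#' passing a function as `recipe` instead re-runs an arbitrary pipeline per
#' fold.
#'
#' @param data data.frame holding the outcome and all predictors.
#' @param outcome name of the outcome column.
#' @param recipe character vector of predictor names (fixed-set recipe), or
#'   a function `f(train_data)` returning an object with a
#'   `predict_fn(test_data)` element.
#' @param plan a [cv_plan()] for `nrow(data)` subjects.
#' @return Numeric vector of out-of-fold predictions, one per subject.
#' @export
kfold_predict <- function(data, outcome, recipe, plan) {
  n <- nrow(data)
  if (length(plan$fold) != n)
    stop("plan does not match the dataset size", call. = FALSE)
  preds <- rep(NA_real_, n)
  for (f in seq_len(plan$k)) {
    test <- plan$fold == f
    train <- !test
    if (is.function(recipe)) {
      model <- recipe(data[train, , drop = FALSE])
      preds[test] <- model$predict_fn(data[test, , drop = FALSE])
    } else {
      if (sum(train) < length(recipe) + 2)
        stop("fold-size error: training fold smaller than predictors + 2",
             call. = FALSE)
      fit <- ols_fit(data[train, recipe, drop = FALSE], data[[outcome]][train])
      preds[test] <- predict_with_equation(fit, data[test, , drop = FALSE])
    }
  }
  preds
}

#' Evaluation report for one prediction method
#'
#' Residuals are oriented as `final - predicted`. Metrics: RMSE
#' (`sqrt(mean(res^2))`); `R2 = 1 - SSE / SST` with
#' `SST = sum((final - mean(final))^2)` (can be negative for methods worse
#' than the mean; the raw-sum-of-squares SST makes the identity
#' `R2 = 1 - n RMSE^2 / SST` exact); RPD = sample SD of the final heights
#' (denominator n - 1) divided by RMSE; residual min / median / IQR / max;
#' bucket percentages of absolute residuals (<= 2 cm, strictly between 2 and
#' 5 cm, >= 5 cm — boundary values fall in the outer buckets); Bland-Altman
#' bias and limits of agreement ([bland_altman()]); and the paired t-test P
#' of [mean_difference_test()] (NA when degenerate).
#'
#' @param final observed final heights (cm).
#' @param predicted predictions (cm), aligned.
#' @param label method name carried in the report.
#' @return List of class `evaluation_report`.
#' @export
evaluate_predictions <- function(final, predicted, label = "method") {
  stopifnot(length(final) == length(predicted))
  n <- length(final)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  sst <- sum((final - mean(final))^2)
  if (sst == 0) stop("undefined R2: zero variance in final height", call. = FALSE)
  res <- final - predicted
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sst
  rpd <- sd(final) / rmse
  ares <- abs(res)
  buckets <- c(le2 = 100 * mean(ares <= 2),
               mid = 100 * mean(ares > 2 & ares < 5),
               ge5 = 100 * mean(ares >= 5))
  ba <- bland_altman(final, predicted)
  tt <- tryCatch(mean_difference_test(final, predicted),
                 error = function(e) list(t = NA_real_, p = NA_real_))
  structure(list(
    method = label, n = n, residuals = res,
    rmse = rmse, r2 = r2, rpd = rpd,
    res_min = min(res), res_median = median(res),
    res_iqr = unname(diff(quantile(res, c(0.25, 0.75)))),
    res_max = max(res),
    buckets = buckets, bland_altman = ba, t_test_p = tt$p),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("<evaluation_report> %s (n = %d)\n",
           "  RMSE %.3f cm | R2 %.3f | RPD %.3f\n",
           "  residuals: min %.3f, median %.3f (IQR %.3f), max %.3f\n",
           "  |res| buckets: <=2 cm %.1f%%, 2-5 cm %.1f%%, >=5 cm %.1f%%\n",
           "  Bland-Altman: bias %.3f, LoA (%.3f, %.3f) | paired-t P %s\n"),
    x$method, x$n, x$rmse, x$r2, x$rpd, x$res_min, x$res_median, x$res_iqr,
    x$res_max, x$buckets["le2"], x$buckets["mid"], x$buckets["ge5"],
    x$bland_altman$mean_diff, x$bland_altman$loa_low, x$bland_altman$loa_high,
    format(x$t_test_p, digits = 3)))
  invisible(x)
}

#' Bland-Altman agreement of predictions with observed final height
#'
#' Differences are oriented `final - predicted` (same orientation as the
#' residuals). Limits of agreement are `mean +/- 1.96 * SD` with the sample
#' SD (denominator n - 1). Per-pair means are returned for plotting.
#'
#' @inheritParams evaluate_predictions
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pair_means`, `differences`.
#' @export
bland_altman <- function(final, predicted) {
  stopifnot(length(final) == length(predicted))
  d <- final - predicted
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       pair_means = (final + predicted) / 2, differences = d)
}

#' Paired t-test of predicted versus observed means
#'
#' Student's t on the paired differences `final - predicted` (each subject is
#' paired with her own prediction). A two-sample (unpaired, Welch) variant is
#' available for sensitivity analysis. Zero-variance differences make the
#' paired statistic undefined and raise an error.
#'
#' @inheritParams evaluate_predictions
#' @param paired paired test (default) or two-sample Welch.
#' @return List with `t` and `p`.
#' @export
mean_difference_test <- function(final, predicted, paired = TRUE) {
  d <- final - predicted
  if (paired && var(d) == 0)
    stop("degenerate: zero-variance differences", call. = FALSE)
  ht <- if (paired) t.test(final, predicted, paired = TRUE)
  else t.test(final, predicted, paired = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Compare all height-prediction methods on one dataset
#'
#' Produces one [evaluate_predictions()] report per method. The three OLS
#' equations are evaluated out-of-fold under a shared [cv_plan()] (the
#' predictor set of each equation is fixed; coefficients are refitted per
#' training fold), while the bone-age projections and the target height are
#' deterministic formulas requiring no fitting:
#' \describe{
#'   \item{ols_eq1}{height at menarche, father's height, mean hand-wrist
#'     (GP) bone age, femur radiomic score.}
#'   \item{ols_eq2}{height at menarche, father's height, GP bone age.}
#'   \item{ols_eq3}{height at menarche, father's height, femur score.}
#'   \item{gp_bp}{projection of height at menarche by GP bone age.}
#'   \item{ph_bp}{projection by knee (PH) bone age.}
#'   \item{target_height}{mid-parental height minus 6.5 cm.}
#' }
#'
#' @param data data.frame with the clinical columns, `femur_score`, and
#'   `final_height` for every subject.
#' @param methods subset of the method names above.
#' @param plan a [cv_plan()]; defaults to a 5-fold plan seeded with 1.
#' @param bp_table percentage-of-mature-height table for the projections.
#' @return List of class `method_comparison`: `reports` (named list) and
#'   `table` (one data.frame row of metrics per method).
#' @export
compare_methods <- function(data,
                            methods = c("ols_eq1", "ols_eq2", "ols_eq3",
                                        "gp_bp", "ph_bp", "target_height"),
                            plan = NULL,
                            bp_table = default_bp_table()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(is.na(data$final_height)))
    stop("coverage error: every subject needs a final height", call. = FALSE)
  if (is.null(plan)) plan <- cv_plan(nrow(data), k = 5, seed = 1)
  recipes <- list(
    ols_eq1 = c("height_menarche", "father_height", "ba_gp_mean", "femur_score"),
    ols_eq2 = c("height_menarche", "father_height", "ba_gp_mean"),
    ols_eq3 = c("height_menarche", "father_height", "femur_score"))
  reports <- list()
  for (mth in methods) {
    pred <- switch(mth,
      ols_eq1 = , ols_eq2 = , ols_eq3 =
        kfold_predict(data, "final_height", recipes[[mth]], plan),
      gp_bp = bp_predict(data$height_menarche, data$ba_gp_mean, bp_table),
      ph_bp = bp_predict(data$height_menarche, data$ba_ph_mean, bp_table),
      target_height = target_height(data$father_height, data$mother_height))
    if (any(is.na(pred)))
      stop("coverage error: method ", mth, " missed a subject", call. = FALSE)
    reports[[mth]] <- evaluate_predictions(data$final_height, pred, mth)
  }
  tab <- do.call(rbind, lapply(reports, function(r) data.frame(
    method = r$method, n = r$n, rmse = r$rmse, r2 = r$r2, rpd = r$rpd,
    res_min = r$res_min, res_median = r$res_median, res_iqr = r$res_iqr,
    res_max = r$res_max,
    pct_le2 = unname(r$buckets["le2"]), pct_2to5 = unname(r$buckets["mid"]),
    pct_ge5 = unname(r$buckets["ge5"]),
    ba_bias = r$bland_altman$mean_diff,
    loa_low = r$bland_altman$loa_low, loa_high = r$bland_altman$loa_high,
    t_test_p = r$t_test_p, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(reports = reports, table = tab), class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Cohort summary table
#'
#' Per-variable minimum, median with quartiles, maximum, mean and SD for the
#' clinical cohort, including the derived height gain
#' (`final_height - height_menarche`), whose mean therefore equals the
#' difference of the two component means exactly.
#'
#' @param clinical clinical data.frame with mean-BA columns (see
#'   [read_clinical_csv()]).
#' @return data.frame, one row per variable.
#' @export
cohort_summary <- function(clinical) {
  df <- clinical
  df$height_gain <- df$final_height - df$height_menarche
  vars <- c("age_menarche", "height_menarche", "father_height",
            "mother_height", "ba_gp_mean", "ba_ph_mean", "final_height",
            "height_gain")
  vars <- intersect(vars, names(df))
  do.call(rbind, lapply(vars, function(v) {
    x <- df[[v]][!is.na(df[[v]])]
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(variable = v, n = length(x), min = min(x), q1 = q[1],
               median = q[2], q3 = q[3], max = max(x), mean = mean(x),
               sd = sd(x), stringsAsFactors = FALSE)
  }))
}
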