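#' Ordinary least squares fit with the full reporting battery
#'
#' Fits `y ~ X` with an intercept and reports, per coefficient, the estimate
#' with 95% CI, t and P, and (for the predictors) the partial correlation
#' with the outcome controlling for the other predictors, via the identity
#' `|r| = |t| / sqrt(t^2 + df_resid)` signed by t. Model-level metrics:
#' R-squared, adjusted R-squared, overall F with P, AIC and BIC. AIC/BIC use
#' the Gaussian profile log-likelihood with the parameter count including the
#' intercept and the error variance (`AIC = -2 logLik + 2 k`,
#' `BIC = -2 logLik + k log(n)`, `k = p + 2`), so values are comparable only
#' within this convention.
#'
#' @param X numeric matrix or data.frame of predictors (named columns);
#'   may have zero columns for the constant model.
#' @param y outcome vector.
#' @return Object of class `equation_fit`: `coefficients` data.frame,
#'   `r2`, `adj_r2`, `f_stat`, `f_p`, `aic`, `bic`, `n`, `sse`, `lm`
#'   (the underlying fit), `predictors`.
#' @export
ols_fit <- function(X, y) {
  df <- as.data.frame(X)
  preds <- names(df)
  n <- length(y)
  if (n <= length(preds) + 1)
    stop("need n > p + 1 observations", call. = FALSE)
  df$.y <- y
  fml <- if (length(preds))
    stats::reformulate(sprintf("`%s`", preds), response = ".y") else .y ~ 1
  fit <- lm(fml, data = df)
  if (fit$rank < length(preds) + 1) {
    alias <- preds[is.na(coef(fit))[-1]]
    stop("collinearity error: rank-deficient design (",
         paste(alias, collapse = ", "), ")", call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- confint(fit)
  dfres <- fit$df.residual
  tvals <- ct[, "t value"]
  partial <- c(NA, tvals[-1] / sqrt(tvals[-1]^2 + dfres))[seq_len(nrow(ct))]
  if (length(preds) == 0) partial <- NA_real_
  partial_p <- ct[, "Pr(>|t|)"]
  partial_p[1] <- NA
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    ci_low = ci[, 1], ci_high = ci[, 2],
    t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
    partial_r = partial, partial_p = partial_p,
    row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  structure(list(
    predictors = preds,
    coefficients = coefs,
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    f_stat = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    f_p = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    aic = AIC(fit), bic = BIC(fit),
    n = n, sse = sum(fit$residuals^2), lm = fit),
    class = "equation_fit")
}

#' @export
print.equation_fit <- function(x, ...) {
  cat(format_equation_fit(x), sep = "\n")
  invisible(x)
}

#' Render an equation fit as a text table
#'
#' Human-readable summary mirroring the usual published layout: per-term
#' estimate with CI, t (P), partial correlation (P), then the model metrics.
#'
#' @param x an `equation_fit`.
#' @return Character vector of lines.
#' @export
format_equation_fit <- function(x) {
  lines <- c(sprintf("OLS equation (n = %d)", x$n),
             sprintf("%-28s %22s %14s %18s", "Term", "Estimate (95% CI)",
                     "t (P)", "Partial r (P)"))
  for (i in seq_len(nrow(x$coefficients))) {
    co <- x$coefficients[i, ]
    lines <- c(lines, sprintf(
      "%-28s %8.3f (%7.3f, %7.3f) %7.2f (%4.2f) %10s",
      co$term, co$estimate, co$ci_low, co$ci_high, co$t, co$p,
      if (is.na(co$partial_r)) "-" else
        sprintf("%5.2f (%4.2f)", co$partial_r, co$partial_p)))
  }
  c(lines,
    sprintf("R2 %.3f | adj R2 %.3f | F %.1f (P %.3g) | AIC %.1f | BIC %.1f",
            x$r2, x$adj_r2, x$f_stat, x$f_p, x$aic, x$bic))
}

#' Predict final height from a fitted equation
#'
#' Applies the linear combination of the fitted coefficients to the supplied
#' predictor values.
#'
#' @param fit an `equation_fit`.
#' @param newdata data.frame (or named list/vector) containing every
#'   predictor of the fit.
#' @return Numeric vector of predictions (cm).
#' @export
predict_with_equation <- function(fit, newdata) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing_p <- setdiff(fit$predictors, names(newdata))
  if (length(missing_p))
    stop("missing predictor(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  b <- fit$coefficients$estimate
  out <- rep(b[1], nrow(newdata))
  for (i in seq_along(fit$predictors))
    out <- out + b[i + 1] * newdata[[fit$predictors[i]]]
  out
}

.check_nested <- function(fit_reduced, fit_full) {
  if (fit_reduced$n != fit_full$n)
    stop("nesting error: fits use different n", call. = FALSE)
  if (!all(fit_reduced$predictors %in% fit_full$predictors))
    stop("nesting error: reduced model is not nested in the full model",
         call. = FALSE)
}

#' Extra-sum-of-squares F-test for nested OLS fits
#'
#' `F = ((SSE_r - SSE_f) / dp) / (SSE_f / df_f)` with `dp` the number of
#' added predictors and `df_f = n - p_full - 1`.
#'
#' @param fit_reduced,fit_full nested `equation_fit`s on the same data.
#' @return List with `f` and `p`.
#' @export
nested_f_test <- function(fit_reduced, fit_full) {
  .check_nested(fit_reduced, fit_full)
  dp <- length(fit_full$predictors) - length(fit_reduced$predictors)
  df_full <- fit_full$n - length(fit_full$predictors) - 1
  if (dp == 0) return(list(f = 0, p = 1))
  f <- ((fit_reduced$sse - fit_full$sse) / dp) / (fit_full$sse / df_full)
  list(f = f, p = pf(f, dp, df_full, lower.tail = FALSE))
}

#' Likelihood-ratio test for nested Gaussian OLS fits
#'
#' Deviance `D = n * log(SSE_reduced / SSE_full)` (twice the Gaussian
#' profile log-likelihood difference), referred to a chi-square with as many
#' degrees of freedom as added predictors.
#'
#' @inheritParams nested_f_test
#' @return List with `d` and `p`.
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full) {
  .check_nested(fit_reduced, fit_full)
  dp <- length(fit_full$predictors) - length(fit_reduced$predictors)
  d <- fit_full$n * log(fit_reduced$sse / fit_full$sse)
  list(d = d, p = if (dp == 0) 1 else pchisq(d, dp, lower.tail = FALSE))
}

#' Huber robust regression compared against OLS
#'
#' Iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345 for 95% Gaussian efficiency), as a robustness check on an OLS fit:
#' with no outliers the two coefficient sets agree closely; gross outliers
#' move OLS but barely move the robust fit.
#'
#' @param X predictors (matrix or data.frame, named columns).
#' @param y outcome.
#' @param tuning Huber tuning constant (default 1.345).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return List with `robust_coefficients`, `ols_coefficients`, and a
#'   `comparison` data.frame (term, ols, robust, difference).
#' @export
huber_fit <- function(X, y, tuning = 1.345, max_iter = 200, tol = 1e-8) {
  df <- as.data.frame(X)
  preds <- names(df)
  df$.y <- y
  fml <- stats::reformulate(sprintf("`%s`", preds), response = ".y")
  rfit <- MASS::rlm(fml, data = df, psi = MASS::psi.huber, k = tuning,
                    maxit = max_iter, acc = tol)
  if (!rfit$converged)
    stop("Huber IRLS did not converge in ", max_iter, " iterations",
         call. = FALSE)
  ofit <- ols_fit(X, y)
  comparison <- data.frame(
    term = ofit$coefficients$term,
    ols = ofit$coefficients$estimate,
    robust = unname(coef(rfit)),
    stringsAsFactors = FALSE)
  comparison$difference <- comparison$robust - comparison$ols
  list(robust_coefficients = coef(rfit),
       ols_coefficients = setNames(ofit$coefficients$estimate,
                                   ofit$coefficients$term),
       comparison = comparison, rlm = rfit)
}

#' Bayley-Pinneau-style projection of final height
#'
#' Divides the current height by the fraction of mature height attained at
#' the given bone age: `predicted = height_now / (pct_mature(bone_age) / 100)`.
#' The percentage is linearly interpolated between table rows; bone ages
#' outside the table range raise an error (no extrapolation).
#'
#' @param height_now current height (cm), positive.
#' @param bone_age bone age (years), within the table's range. Vectorized.
#' @param table a `bp_table` from [read_bp_table()] /
#'   [default_bp_table()].
#' @return Predicted final height(s), cm.
#' @export
bp_predict <- function(height_now, bone_age, table = default_bp_table()) {
  if (any(height_now <= 0)) stop("height_now must be positive", call. = FALSE)
  rng <- range(table$bone_age)
  if (any(bone_age < rng[1] | bone_age > rng[2]))
    stop(sprintf("bone_age outside table range [%g, %g]; no extrapolation",
                 rng[1], rng[2]), call. = FALSE)
  pct <- stats::approx(table$bone_age, table$pct_mature, xout = bone_age,
                       method = "linear", ties = "ordered")$y
  height_now / (pct / 100)
}

#' Mid-parental target height for a girl
#'
#' `(father + mother) / 2 - 6.5` cm, the girls' sex adjustment of the
#' mid-parental height.
#'
#' @param father_cm,mother_cm parental heights in cm (100-220).
#' @return Target height, cm. Vectorized.
#' @export
target_height <- function(father_cm, mother_cm) {
  if (any(father_cm < 100 | father_cm > 220 | mother_cm < 100 | mother_cm > 220))
    stop("parental heights must lie in [100, 220] cm", call. = FALSE)
  (father_cm + mother_cm) / 2 - 6.5
}
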