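#' Variance threshold filter
#'
#' Drops features whose sample variance is at or below the threshold
#' (strict `>` keeps a feature). By default the variance is computed on the
#' raw feature values — the convention of the usual filter-based selectors —
#' because a bounded normalization (min-max to `[0, 1]`) caps the variance at
#' 0.25 and would make the customary 0.8 threshold remove everything, while
#' z-scoring forces every variance to 1 and removes nothing. Both alternative
#' conventions remain selectable for sensitivity analyses and the choice is
#' recorded in the result.
#'
#' @param x feature matrix (subjects x features, named columns).
#' @param threshold variance threshold (default 0.8).
#' @param normalization `"none"` (default), `"zscore"`, or `"minmax"` applied
#'   before the variance is measured.
#' @return Character vector of surviving feature names, with the applied
#'   convention in attributes `threshold` and `normalization`.
#' @export
variance_filter <- function(x, threshold = 0.8,
                            normalization = c("none", "zscore", "minmax")) {
  normalization <- match.arg(normalization)
  x <- as.matrix(x)
  xs <- switch(normalization,
    none = x,
    zscore = scale(x),
    minmax = apply(x, 2, function(v) {
      rg <- max(v) - min(v)
      if (rg == 0) v * 0 else (v - min(v)) / rg
    }))
  v <- apply(xs, 2, var)
  v[is.na(v)] <- 0
  keep <- colnames(x)[v > threshold]
  attr(keep, "threshold") <- threshold
  attr(keep, "normalization") <- normalization
  keep
}

#' Univariate F-test screen
#'
#' For each feature, the F-test of the simple linear regression of the
#' outcome on that feature (equivalently the squared t of the slope) is
#' computed; features with P below `alpha` survive. Zero-variance features
#' are excluded with a warning.
#'
#' @param x feature matrix (subjects x features).
#' @param y outcome vector (final height, cm).
#' @param alpha retention threshold on the univariate P value (default 0.05).
#' @return data.frame with `feature`, `f_score`, `p_value`, `keep`.
#' @export
univariate_screen <- function(x, y, alpha = 0.05) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  n <- length(y)
  if (n <= 3) stop("need more than 3 subjects", call. = FALSE)
  sy <- y - mean(y)
  res <- lapply(colnames(x), function(j) {
    v <- x[, j]
    if (var(v) == 0) {
      warning("zero-variance feature excluded from screen: ", j, call. = FALSE)
      return(data.frame(feature = j, f_score = NA_real_, p_value = NA_real_,
                        keep = FALSE, stringsAsFactors = FALSE))
    }
    sv <- v - mean(v)
    r2 <- sum(sv * sy)^2 / (sum(sv^2) * sum(sy^2))
    f <- r2 / (1 - r2) * (n - 2)
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
    data.frame(feature = j, f_score = f, p_value = p, keep = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' LASSO feature selection and score definition
#'
#' Fits an L1-penalized least-squares path (coordinate descent via glmnet) on
#' standardized features, chooses the penalty by k-fold cross-validation
#' (minimum-MSE rule by default; the 1-SE rule by flag) under a fixed seed,
#' and returns the non-zero-coefficient terms as a [score_definition()].
#' Standardization uses the means and SDs of the data supplied here (the
#' training set), which are stored so the score can be applied honestly to
#' new subjects.
#'
#' @param x feature matrix (subjects x features, named columns).
#' @param y outcome vector (final height, cm).
#' @param site anatomical site label stored in the definition.
#' @param nfolds folds for the penalty cross-validation (default 10).
#' @param rule `"min"` (minimum CV-MSE, default) or `"1se"`.
#' @param seed integer seed for the CV fold draw (default 20180801).
#' @param lambda optional fixed penalty, bypassing cross-validation; `0`
#'   reproduces the least-squares solution when it is identifiable.
#' @return A `score_definition`. If every coefficient is zero at the chosen
#'   penalty, an intercept-only definition is returned with a warning.
#' @export
lasso_select <- function(x, y, site = "distal_femur", nfolds = 10,
                         rule = c("min", "1se"), seed = 20180801,
                         lambda = NULL) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  usable <- sdv > 0
  xs <- scale(x[, usable, drop = FALSE], center = mu[usable],
              scale = sdv[usable])
  if (is.null(lambda)) {
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(xs, y, alpha = 1, nfolds = nfolds,
                               standardize = FALSE)
    lambda <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
    fit <- cvfit$glmnet.fit
  } else {
    fit <- glmnet::glmnet(xs, y, alpha = 1, standardize = FALSE,
                          lambda = if (lambda == 0) c(0.5, 0) else lambda,
                          thresh = 1e-12)
  }
  cf <- as.matrix(coef(fit, s = lambda, exact = FALSE))[, 1]
  terms <- cf[-1][cf[-1] != 0]
  if (length(terms) == 0)
    warning("empty signature: all coefficients zero at the chosen penalty",
            call. = FALSE)
  score_definition(
    site = site,
    intercept = cf[1],
    coefficients = terms,
    standardization = data.frame(feature = names(terms),
                                 mean = mu[names(terms)],
                                 sd = sdv[names(terms)],
                                 row.names = NULL),
    lambda = lambda)
}
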