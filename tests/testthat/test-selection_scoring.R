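test_that("ICC forms behave as agreement and consistency coefficients", {
  set.seed(31)
  x <- rnorm(50, 10, 2)
  expect_equal(icc_two_way(cbind(x, x), "ICC2"), 1)
  # absolute agreement penalizes a constant offset; consistency does not
  expect_lt(icc_two_way(cbind(x, x + 3), "ICC2"), 0.8)
  expect_equal(icc_two_way(cbind(x, x + 3), "ICC3"), 1)
  # independent raters: ICC near 0 (Monte-Carlo at n = 2000)
  icc0 <- icc_two_way(cbind(rnorm(2000), rnorm(2000)), "ICC2")
  expect_lt(abs(icc0), 0.08)
  expect_error(icc_two_way(matrix(5, 10, 2)), "degenerate")
  expect_error(icc_two_way(matrix(rnorm(8), 4, 2)), "at least 5 subjects")
})

test_that("stability gate passes reproducible features and fails noisy ones", {
  set.seed(33)
  n <- 60
  stable <- rnorm(n, 100, 10)
  noisy_a <- rnorm(n); noisy_b <- rnorm(n)
  mk <- function(stab, noise) {
    m <- cbind(stable_f = stab, noisy_f = noise)
    rownames(m) <- sprintf("S%02d", 1:n)
    m
  }
  inter_a <- mk(stable, noisy_a)
  inter_b <- mk(stable + rnorm(n, 0, 0.5), noisy_b)
  intra_a <- inter_a
  intra_b <- mk(stable + rnorm(n, 0, 0.5), rnorm(n))
  rep <- stability_filter(inter_a, inter_b, intra_a, intra_b)
  expect_true(rep$pass[rep$feature == "stable_f"])
  expect_false(rep$pass[rep$feature == "noisy_f"])
  # threshold 1 fails everything except exact ties
  rep1 <- stability_filter(inter_a, inter_b, intra_a, intra_b, threshold = 1)
  expect_false(any(rep1$pass))
  # identical matrices pass at any threshold below 1
  repi <- stability_filter(inter_a, inter_a, inter_a, inter_a)
  expect_true(all(repi$pass))
  # misalignment
  bad <- inter_b; rownames(bad)[1] <- "ZZ"
  expect_error(stability_filter(inter_a, bad, intra_a, intra_b), "alignment")
})

test_that("variance filter keeps strictly-above-threshold features", {
  set.seed(35)
  x <- cbind(const = rep(1, 40),
             low = rnorm(40, sd = sqrt(0.5)),
             boundary = as.numeric(scale(rnorm(40))) * sqrt(0.81) + 5,
             high = rnorm(40, sd = 10))
  # boundary column built to have sample variance exactly 0.81
  keep <- variance_filter(x, threshold = 0.8)
  expect_false("const" %in% keep)
  expect_true("boundary" %in% keep)   # strict >
  expect_true("high" %in% keep)
  expect_equal(attr(keep, "normalization"), "none")
  # z-scoring forces unit variance: everything but constants survives
  keepz <- variance_filter(x, threshold = 0.8, normalization = "zscore")
  expect_setequal(keepz, c("low", "boundary", "high"))
  # min-max caps variance at 0.25: nothing survives a 0.8 threshold
  expect_length(variance_filter(x, 0.8, normalization = "minmax"), 0)
})

test_that("univariate screen is an F-test with the t-squared identity", {
  set.seed(37)
  n <- 80
  y <- rnorm(n, 160, 4)
  x <- cbind(self = y, indep = rnorm(n))
  sc <- univariate_screen(x, y)
  expect_true(sc$keep[sc$feature == "self"])
  expect_lt(sc$p_value[sc$feature == "self"], 1e-12)
  # F equals squared t of the simple regression slope
  tt <- summary(lm(y ~ x[, "indep"]))$coefficients[2, "t value"]
  expect_equal(sc$f_score[sc$feature == "indep"], tt^2, tolerance = 1e-10)
  expect_warning(univariate_screen(cbind(k = rep(2, n)), y), "zero-variance")
})

test_that("univariate screen holds its type-I error near alpha", {
  set.seed(39)
  n <- 173
  y <- rnorm(n)
  x <- matrix(rnorm(n * 1000), n, 1000,
              dimnames = list(NULL, paste0("f", 1:1000)))
  sc <- univariate_screen(x, y, alpha = 0.05)
  expect_lt(abs(mean(sc$keep) - 0.05), 0.02)
})

test_that("LASSO selection recovers signals and respects penalty limits", {
  set.seed(41)
  n <- 120
  x <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- 3 * x[, 1] + rnorm(n, 0, 0.5)
  # huge penalty: empty signature
  expect_warning(d_inf <- lasso_select(x, y, lambda = 1e6),
                 "empty signature")
  expect_length(d_inf$coefficients, 0)
  # zero penalty reproduces least squares on standardized features
  d0 <- lasso_select(x, y, lambda = 0)
  xs <- scale(x)
  bls <- coef(lm(y ~ xs))
  expect_equal(unname(d0$coefficients[paste0("f", 1:20)]),
               unname(bls[-1]), tolerance = 1e-5)
  expect_equal(d0$intercept, unname(bls[1]), tolerance = 1e-6)
  # CV-chosen penalty keeps the true feature (deterministic under the seed)
  d_cv <- lasso_select(x, y)
  expect_true("f1" %in% names(d_cv$coefficients))
  d_cv2 <- lasso_select(x, y)
  expect_identical(d_cv$coefficients, d_cv2$coefficients)
})

test_that("LASSO finds a lone true feature among many noise features", {
  set.seed(43)
  hits <- 0
  reps <- 25
  for (i in 1:reps) {
    n <- 200
    x <- matrix(rnorm(n * 51), n, 51,
                dimnames = list(NULL, c("true", paste0("noise", 1:50))))
    y <- 3 * x[, "true"] + rnorm(n)
    d <- lasso_select(x, y, seed = 500 + i)
    if ("true" %in% names(d$coefficients)) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("the signed-log score obeys its defining identities", {
  def <- score_definition("distal_femur", intercept = 0,
                          coefficients = c(a = 1),
                          standardization = NULL)
  sc <- function(v) radiomic_score(def, c(a = v))
  expect_equal(sc(1)$score, 0)
  expect_equal(sc(-1)$score, 0)
  for (v in c(0.5, 2, 10, 160)) {
    expect_equal(sc(-v)$score, -sc(v)$score)  # odd in S
  }
  expect_equal(sc(exp(2))$score, 2)
  expect_error(sc(1e-12), "near-singular")
  expect_error(radiomic_score(def, c(b = 1)), "missing feature")
})

test_that("the shipped reference signature evaluates as printed", {
  def <- reference_score_definition("distal_femur")
  expect_equal(def$intercept, 160.0959)
  # zero feature contribution leaves S at the intercept
  feats <- setNames(rep(0, length(def$coefficients)),
                    names(def$coefficients))
  out <- radiomic_score(def, feats)
  expect_equal(out$S, 160.0959)
  expect_equal(out$score, log(160.0959), tolerance = 1e-12)
  # round-trip through the CSV serialization
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_csv(def, path)
  back <- read_score_csv(path, "distal_femur")
  expect_equal(back$coefficients, def$coefficients)
  expect_equal(back$intercept, def$intercept)
  # tibia definition shares the printed intercept
  expect_equal(reference_score_definition("proximal_tibia")$intercept,
               160.0959)
})

test_that("the selection cascade only ever shrinks the feature set", {
  set.seed(47)
  n <- 60
  p <- 30
  x <- matrix(rnorm(n * p, sd = rep(c(0.5, 2), each = n * p / 2)), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- 2 * x[, p] + rnorm(n)
  kept_var <- variance_filter(x, threshold = 0.8)
  expect_lte(length(kept_var), p)
  uni <- univariate_screen(x[, kept_var, drop = FALSE], y)
  kept_uni <- uni$feature[uni$keep]
  expect_true(all(kept_uni %in% kept_var))
  if (length(kept_uni) >= 2) {
    def <- lasso_select(x[, kept_uni, drop = FALSE], y)
    expect_true(all(names(def$coefficients) %in% kept_uni))
  }
})
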