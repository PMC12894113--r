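test_that("OLS fit reproduces exact and oracle solutions", {
  # noiseless line
  x <- 1:10
  f <- suppressWarnings(ols_fit(data.frame(x = x), 2 * x + 1))
  expect_equal(f$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(f$r2, 1)

  # random instance vs normal-equations oracle
  set.seed(51)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(0.5, -2, 1) + rnorm(n)
  f2 <- ols_fit(as.data.frame(X), y)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(f2$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-8)

  # R2 invariant under predictor rescaling
  f3 <- ols_fit(data.frame(a = X[, 1] * 1000, b = X[, 2], c = X[, 3]), y)
  expect_equal(f3$r2, f2$r2, tolerance = 1e-12)

  # partial-correlation identity |r| = |t| / sqrt(t^2 + df)
  dfres <- f2$n - 3 - 1
  for (i in 2:4) {
    tt <- f2$coefficients$t[i]
    expect_equal(abs(f2$coefficients$partial_r[i]),
                 abs(tt) / sqrt(tt^2 + dfres), tolerance = 1e-10)
    expect_equal(sign(f2$coefficients$partial_r[i]), sign(tt))
  }
  expect_lte(f2$adj_r2, f2$r2)

  # collinearity is reported with the offending column
  expect_error(ols_fit(data.frame(a = X[, 1], a2 = 2 * X[, 1]), y),
               "collinearity")
})

test_that("nested F and likelihood-ratio tests match their SSE formulas", {
  set.seed(53)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X$a + rnorm(n)
  fr <- ols_fit(X["a"], y)
  ff <- ols_fit(X, y)
  ft <- nested_f_test(fr, ff)
  f_hand <- ((fr$sse - ff$sse) / 1) / (ff$sse / (n - 3))
  expect_equal(ft$f, f_hand, tolerance = 1e-8)
  # cross-check against anova() as an independent route
  av <- anova(fr$lm, ff$lm)
  expect_equal(ft$f, av$F[2], tolerance = 1e-10)
  expect_equal(ft$p, av$`Pr(>F)`[2], tolerance = 1e-10)

  expect_equal(nested_f_test(ff, ff)$f, 0)
  lr <- likelihood_ratio_test(fr, ff)
  expect_equal(lr$d, n * log(fr$sse / ff$sse), tolerance = 1e-10)
  expect_gte(lr$d, 0)
  expect_equal(likelihood_ratio_test(ff, ff)$d, 0)
  expect_error(nested_f_test(ff, fr), "nesting")

  # a noiseless perfect predictor drives the incremental P to ~0
  y2 <- X$a + 0.001 * rnorm(n)
  fr2 <- ols_fit(X["b"], y2); ff2 <- ols_fit(X[c("b", "a")], y2)
  expect_lt(nested_f_test(fr2, ff2)$p, 1e-20)
})

test_that("Huber regression agrees with OLS on clean data, resists outliers", {
  set.seed(55)
  n <- 50
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n, 0, 0.5)
  h <- huber_fit(data.frame(x = x), y)
  se <- summary(ols_fit(data.frame(x = x), y)$lm)$coefficients[, "Std. Error"]
  expect_lt(max(abs(h$comparison$difference) / se), 2)

  better <- 0
  for (i in 1:40) {
    set.seed(100 + i)
    x <- rnorm(n); y <- 1 + 2 * x + rnorm(n, 0, 0.5)
    y[1] <- y[1] + 40  # gross outlier
    h2 <- huber_fit(data.frame(x = x), y)
    if (abs(h2$comparison$robust[2] - 2) < abs(h2$comparison$ols[2] - 2))
      better <- better + 1
  }
  expect_gte(better / 40, 0.9)
})

test_that("bone-age projection divides by the interpolated percentage", {
  tab <- validate_bp_table(data.frame(bone_age = c(12, 13, 14),
                                      pct_mature = c(95, 97, 99)))
  expect_equal(bp_predict(150, 12, tab), 150 / 0.95)
  expect_equal(bp_predict(150, 12.5, tab), 150 / 0.96)  # midpoint -> 96
  tab100 <- validate_bp_table(data.frame(bone_age = c(15, 16),
                                         pct_mature = c(100, 100)))
  expect_equal(bp_predict(163.2, 15.5, tab100), 163.2)  # maturity limit
  expect_error(bp_predict(150, 11, tab), "outside table range")
  expect_error(bp_predict(-1, 12, tab), "positive")
})

test_that("target height is the adjusted mid-parental mean", {
  expect_equal(target_height(172, 160), 159.5)
  expect_equal(target_height(155, 148), 145)
  expect_equal(target_height(160, 172), target_height(172, 160))
  expect_error(target_height(95, 160), "\\[100, 220\\]")
})

test_that("equation prediction applies the linear combination", {
  hand <- suppressWarnings(
    ols_fit(data.frame(h = c(140, 150, 160, 170, 155)),
            0.7 * c(140, 150, 160, 170, 155) + 50))
  expect_equal(predict_with_equation(hand, data.frame(h = 150)), 155)
  # on its own training rows, residuals sum to zero
  set.seed(57)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y <- 1 + X$a - X$b + rnorm(20)
  f <- ols_fit(X, y)
  expect_equal(sum(y - predict_with_equation(f, X)), 0, tolerance = 1e-9)
  expect_error(predict_with_equation(f, data.frame(a = 1)),
               "missing predictor")
  # intercept-only fit returns the intercept
  f0 <- ols_fit(data.frame(matrix(numeric(0), nrow = 20, ncol = 0)), y)
  expect_equal(predict_with_equation(f0, data.frame(a = 1:3)),
               rep(mean(y), 3))
})
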