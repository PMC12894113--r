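test_that("wavelet bands have unit-DC low-pass and vanishing high-pass", {
  const <- matrix(7.3, 16, 16)
  expect_lt(max(abs(wavelet_filter(const, "H"))), 1e-9)
  expect_lt(max(abs(wavelet_filter(const, "L") - 7.3)), 1e-9)  # forced gain 1
  set.seed(4)
  img <- matrix(runif(256, 0, 255), 16, 16)
  expect_identical(wavelet_filter(img, "L"), wavelet_filter(img, "L"))
  expect_false(isTRUE(all.equal(wavelet_filter(img, "L"),
                                wavelet_filter(img, "H"))))
  expect_error(wavelet_filter(matrix(1, 4, 4), "L"), "at least 8 x 8")
})

test_that("discretization follows the fixed-bin-width floor rule", {
  vals <- matrix(10, 4, 4)
  vals[1, 1:4] <- c(0, 24, 25, 49)
  d <- discretize(roi_from(vals), bin_width = 25)
  expect_equal(d$levels[1, ], c(1, 1, 2, 2))
  expect_equal(d$ng, 2)
  dc <- discretize(roi_from(matrix(42, 5, 5)), 25)
  expect_equal(dc$ng, 1)
  expect_true(all(dc$levels == 1))
  expect_error(discretize(roi_from(vals), bin_width = 0), "positive")
})

test_that("first-order features match hand arithmetic", {
  vals <- matrix(1, 4, 4)
  vals[1, ] <- c(1, 2, 3, 4)
  mask <- matrix(0, 4, 4); mask[1, ] <- 1
  # mask needs >= 16 px for roi_image; use a padded variant for the small set
  roi <- structure(list(pixels = vals, mask = mask == 1), class = "roi_image")
  fo <- firstorder_features(roi)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Median"]], 2.5)
  expect_equal(fo[["Minimum"]], 1)
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Variance"]], 1.25)  # N denominator

  m100 <- roi_from(matrix(1:100, 10, 10))
  fo100 <- firstorder_features(m100)
  expect_equal(fo100[["10Percentile"]], 10.9)  # linear interpolation
  expect_equal(fo100[["InterquartileRange"]], 75.25 - 25.75)
  # RobustMeanAbsoluteDeviation: values within [P10, P90] = 10.9..90.1
  inner <- (1:100)[1:100 >= 10.9 & 1:100 <= 90.1]
  expect_equal(fo100[["RobustMeanAbsoluteDeviation"]],
               mean(abs(inner - mean(inner))))

  foc <- firstorder_features(roi_from(matrix(5, 5, 5)))
  expect_equal(unname(foc[c("Variance", "Range")]), c(0, 0))
  expect_equal(unname(foc[c("Mean", "Median", "Minimum")]), c(5, 5, 5))
})

test_that("shape features follow the stated pixel conventions", {
  row10 <- matrix(0, 5, 12); row10[3, 2:11] <- 1
  s <- shape2d_features(row10)
  expect_equal(s[["MaximumDiameter"]], 9)  # brute-force max pair distance
  expect_equal(s[["PixelSurface"]], 10)
  expect_equal(s[["Perimeter"]], 22)  # 2*10 + 2*1 crack edges

  sq <- matrix(0, 12, 12); sq[2:11, 2:11] <- 1
  expect_equal(shape2d_features(sq)[["Perimeter"]], 40)

  single <- matrix(0, 3, 3); single[2, 2] <- 1
  expect_equal(shape2d_features(single)[["MaximumDiameter"]], 0)
  expect_error(shape2d_features(matrix(0, 3, 3)), "empty ROI")

  # disconnected mask: largest component wins
  two <- matrix(0, 8, 8); two[2:5, 2:5] <- 1; two[7, 7] <- 1
  expect_equal(shape2d_features(two)[["PixelSurface"]], 16)
})

test_that("extract_all produces aligned, deterministic, complete key sets", {
  roi1 <- rendered_roi(m = 0.2, seed = 11)
  roi2 <- rendered_roi(m = -1.0, seed = 12)
  cfg <- extraction_config()
  f1 <- extract_all(roi1, cfg); f2 <- extract_all(roi2, cfg)
  expect_identical(names(f1), names(f2))
  expect_true(all(is.finite(f1)))
  expect_identical(as.numeric(f1), as.numeric(extract_all(roi1, cfg)))
  # every key of the shipped reference signature must be extractable
  for (site in c("distal_femur", "proximal_tibia")) {
    def <- reference_score_definition(site)
    expect_true(all(names(def$coefficients) %in% names(f1)),
                label = paste("coverage for", site))
  }
})

test_that("texture features are invariant to a constant intensity shift", {
  roi <- rendered_roi(m = 0, seed = 21)
  d1 <- discretize(roi, 25)
  roi2 <- roi; roi2$pixels <- roi$pixels + 37.5
  d2 <- discretize(roi2, 25)
  expect_identical(d1$levels, d2$levels)
  expect_equal(glcm_features(d1), glcm_features(d2))
  expect_equal(glrlm_features(d1), glrlm_features(d2))
})

test_that("feature matrices serialize to aligned tidy and wide CSV", {
  roi1 <- rendered_roi(m = 0.2, seed = 11)
  roi2 <- rendered_roi(m = -1.0, seed = 12)
  cfg <- extraction_config()
  m <- feature_matrix(list(extract_all(roi1, cfg), extract_all(roi2, cfg)),
                      subject_ids = c("A", "B"))
  dir <- withr::local_tempdir()
  paths <- write_feature_matrix(m, "distal_femur", dir, cfg)
  wide <- read.csv(paths[["wide"]], check.names = FALSE)
  expect_equal(wide$subject_id, c("A", "B"))
  expect_equal(as.numeric(wide[1, -1]), as.numeric(m[1, ]))
  tidy <- read.csv(paths[["tidy"]])
  expect_equal(nrow(tidy), 2 * ncol(m))
  expect_setequal(unique(tidy$feature_class),
                  c("shape2d", "firstorder", "glcm", "glrlm", "glszm",
                    "gldm", "ngtdm"))
  cfg_back <- jsonlite::read_json(paths[["config"]], simplifyVector = TRUE)
  expect_equal(cfg_back$bin_width, 25)
})
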