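test_that("GLCM features match the hand-enumerated small cases", {
  # constant 3x3 ROI: single level
  g <- glcm_features(droi(matrix(1L, 3, 3)))
  expect_equal(g[["JointAverage"]], 1)
  expect_equal(g[["ClusterProminence"]], 0)
  expect_equal(g[["SumAverage"]], 2)

  # 2x2 grid [[1,1],[2,2]] against the brute-force oracle
  lev <- matrix(c(1L, 2L, 1L, 2L), 2, 2)
  expect_equal(glcm_features(droi(lev)), oracle_glcm(lev), tolerance = 1e-12)

  # symmetry identity: SumAverage = 2 * JointAverage
  set.seed(7)
  for (i in 1:10) {
    d <- random_droi()
    f <- glcm_features(d)
    expect_equal(f[["SumAverage"]], 2 * f[["JointAverage"]],
                 tolerance = 1e-12)
  }
})

test_that("GLRLM run accounting conserves pixels and matches hand cases", {
  # 1x4 constant row: horizontal direction has a single run of length 4
  lev <- matrix(c(1L, 1L, 1L, 1L), 1, 4)
  mats <- glrlm_matrices(droi(lev))
  horiz <- mats[[1]]
  expect_equal(sum(horiz), 1)
  expect_equal(horiz[1, 4], 1)
  expect_equal(sum(rowSums(horiz)^2) / sum(horiz), 1)  # GLN
  expect_equal(sum(colSums(horiz)^2) / sum(horiz), 1)  # RLN
  expect_equal(sum(horiz %*% (seq_len(ncol(horiz))^2)) / sum(horiz), 16)  # LRE

  # alternating row: no two equal neighbors in any direction, all runs 1
  alt <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  f <- glrlm_features(droi(alt))
  expect_equal(f[["LongRunEmphasis"]], 1)
  expect_equal(f[["ShortRunEmphasis"]], 1)
  # a 2-level checkerboard still has unit runs along both axes (its
  # diagonals, by contrast, are constant)
  cb <- matrix(as.integer(outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1)),
               4, 4)
  mats <- glrlm_matrices(droi(cb))
  for (M in mats[c(1, 2)]) expect_equal(ncol(M), 1)  # horizontal, vertical

  # conservation: sum_g,r R(g,r) * r = foreground count, per direction
  set.seed(11)
  for (i in 1:20) {
    d <- random_droi()
    for (M in glrlm_matrices(d)) {
      expect_equal(sum(M %*% seq_len(ncol(M))), sum(d$mask))
    }
  }
})

test_that("GLSZM zones conserve pixels and match hand cases", {
  # constant ROI: one zone of size n
  d <- droi(matrix(1L, 3, 4))
  Z <- glszm_matrix(d)
  expect_equal(sum(Z), 1)
  f <- glszm_features(d)
  expect_equal(f[["SizeZoneNonUniformity"]], 1)
  expect_equal(f[["LargeAreaEmphasis"]], 144)

  # two disjoint same-level blobs of sizes 3 and 5
  lev <- matrix(0L, 5, 7)
  lev[1, 1:3] <- 1L
  lev[4:5, 5:6] <- 1L; lev[5, 7] <- 1L
  f2 <- glszm_features(droi(lev))
  expect_equal(f2[["LargeAreaEmphasis"]], (9 + 25) / 2)

  # conservation: sum Z(g,s) * s = foreground count
  set.seed(13)
  for (i in 1:20) {
    d <- random_droi()
    Z <- glszm_matrix(d)
    expect_equal(sum(Z %*% seq_len(ncol(Z))), sum(d$mask))
  }
})

test_that("GLDM dependence counts match neighbor enumeration", {
  # constant 3x3: center 8 neighbors, corners 3, edges 5
  D <- gldm_matrix(droi(matrix(1L, 3, 3)))
  expect_equal(sum(D), 9)                 # conservation
  expect_equal(D[1, 8 + 1], 1)            # center (dependence 8)
  expect_equal(D[1, 3 + 1], 4)            # corners
  expect_equal(D[1, 5 + 1], 4)            # edges

  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  Ds <- gldm_matrix(droi(single))
  expect_equal(sum(Ds), 1)
  expect_equal(Ds[1, 1], 1)               # dependence 0 -> index 1

  set.seed(17)
  for (i in 1:20) {
    d <- random_droi()
    expect_equal(sum(gldm_matrix(d)), sum(d$mask))
  }
})

test_that("NGTDM s-values match hand-computed neighbor means", {
  # constant ROI: complexity 0
  f <- ngtdm_features(droi(matrix(2L, 3, 3)))
  expect_equal(f[["Complexity"]], 0)

  # 1x3 row (1,2,1): s1 = |1-2| + |1-2| = 2 ; s2 = |2-1| = 1
  tab <- ngtdm_table(droi(matrix(c(1L, 2L, 1L), 1, 3)))
  expect_equal(tab$s, c(2, 1))
  expect_equal(tab$p, c(2 / 3, 1 / 3))

  set.seed(19)
  for (i in 1:20) {
    expect_gte(ngtdm_features(random_droi())[["Complexity"]], 0)
  }
})

test_that("all five texture families equal the brute-force oracle on random ROIs", {
  set.seed(23)
  for (i in 1:25) {
    d <- random_droi(6, 6, ng = sample(2:4, 1))
    lev <- d$levels
    expect_equal(glcm_features(d), oracle_glcm(lev), tolerance = 1e-12)
    expect_equal(glrlm_features(d), oracle_glrlm(lev), tolerance = 1e-12)
    expect_equal(glszm_features(d), oracle_glszm(lev), tolerance = 1e-12)
    expect_equal(gldm_features(d), oracle_gldm(lev), tolerance = 1e-12)
    expect_equal(ngtdm_features(d), oracle_ngtdm(lev), tolerance = 1e-12)
  }
})
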