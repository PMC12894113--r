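# Gray-level texture-matrix features on a discretized ROI.
#
# Conventions (the dominant 2D choices, applied uniformly):
#  * GLCM and GLRLM use the 4 planar directions at distance 1
#    (0, 45, 90, 135 degrees); the GLCM is symmetric; per-direction feature
#    values are averaged.
#  * GLSZM zones and GLDM dependences use 8-connectivity.
#  * GLDM dependence tolerance alpha = 0 (exact level match); the dependence
#    index is stored as count + 1 so small-dependence emphases never divide
#    by zero.
#  * NGTDM neighborhood = the valid 8-neighbors inside the mask.

.DIRECTIONS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# shifted copy of the level matrix; 0 (background) outside
.shift_levels <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  out <- matrix(0L, nr, nc)
  r0 <- max(1, 1 + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1, 1 + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(out)
  out[(r0:r1) - dr, (c0:c1) - dc] <- lev[r0:r1, c0:c1]
  out
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric GLCMs at distance 1 for the 4 planar directions; each matrix is
#' normalized and features are computed per direction, then averaged.
#' With `p(i, j)` the normalized symmetric matrix and `mu = sum(i * p(i, j))`:
#' `JointAverage = sum(i * p)`, `SumAverage = sum((i + j) * p)` (twice the
#' joint average for a symmetric matrix), `Contrast = sum((i - j)^2 p)`,
#' `ClusterProminence = sum((i + j - 2 mu)^4 p)`, and
#' `JointEntropy = -sum(p log2 p)` over non-zero cells.
#'
#' @param d a `discretized_roi` from [discretize()].
#' @return Named numeric vector of direction-averaged features.
#' @export
glcm_features <- function(d) {
  mats <- glcm_matrices(d)
  per_dir <- vapply(mats, function(P) {
    i <- row(P); j <- col(P)
    mu <- sum(i * P)
    nz <- P > 0
    c(JointAverage = mu,
      SumAverage = sum((i + j) * P),
      Contrast = sum((i - j)^2 * P),
      ClusterProminence = sum((i + j - 2 * mu)^4 * P),
      JointEntropy = -sum(P[nz] * log2(P[nz])))
  }, numeric(5))
  rowMeans(per_dir)
}

#' @rdname glcm_features
#' @return `glcm_matrices()` returns the list of 4 normalized symmetric
#'   co-occurrence matrices (one per direction).
#' @export
glcm_matrices <- function(d) {
  if (sum(d$mask) == 0) stop("empty ROI", call. = FALSE)
  ng <- d$ng
  lapply(.DIRECTIONS, function(dd) {
    sh <- .shift_levels(d$levels, dd[1], dd[2])
    ok <- d$levels > 0 & sh > 0
    M <- matrix(0, ng, ng)
    if (any(ok)) {
      tab <- table(factor(d$levels[ok], levels = 1:ng),
                   factor(sh[ok], levels = 1:ng))
      M <- unclass(tab) + t(unclass(tab))  # symmetrize
      M <- M / sum(M)
    } else {
      # no pairs in this direction (degenerate thin ROI): identity-like fallback
      M[1, 1] <- 1
    }
    M
  })
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices `R(g, r)` for the 4 planar directions (runs are maximal
#' same-level segments inside the mask; out-of-mask pixels break runs);
#' features per direction, then averaged. With `Nr = sum(R)` and
#' `p = R / Nr`: `ShortRunEmphasis = sum(p / r^2)`,
#' `LongRunEmphasis = sum(p r^2)`, `GrayLevelNonUniformity =
#' sum_g (sum_r R)^2 / Nr`, `RunLengthNonUniformity = sum_r (sum_g R)^2 / Nr`,
#' `ShortRunHighGrayLevelEmphasis = sum(p g^2 / r^2)`, `GrayLevelVariance` =
#' variance of `g` under the run-weighted marginal, and `RunPercentage =
#' Nr / Np` with `Np` the foreground pixel count.
#'
#' @inheritParams glcm_features
#' @export
glrlm_features <- function(d) {
  mats <- glrlm_matrices(d)
  np <- sum(d$mask)
  per_dir <- vapply(mats, function(R) .rlm_stats(R, np), numeric(7))
  rowMeans(per_dir)
}

.rlm_stats <- function(R, np) {
  nr_runs <- sum(R)
  g <- row(R); r <- col(R)
  p <- R / nr_runs
  mu_g <- sum(g * p)
  c(ShortRunEmphasis = sum(p / r^2),
    LongRunEmphasis = sum(p * r^2),
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr_runs,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr_runs,
    ShortRunHighGrayLevelEmphasis = sum(p * g^2 / r^2),
    GrayLevelVariance = sum((g - mu_g)^2 * p),
    RunPercentage = nr_runs / np)
}

#' @rdname glrlm_features
#' @return `glrlm_matrices()` returns the list of 4 run-length matrices
#'   (gray level x run length, raw counts).
#' @export
glrlm_matrices <- function(d) {
  if (sum(d$mask) == 0) stop("empty ROI", call. = FALSE)
  lev <- d$levels
  nr <- nrow(lev); nc <- ncol(lev)
  max_run <- max(nr, nc)
  lines_for <- function(dir) {
    switch(dir,
      h = lapply(seq_len(nr), function(i) lev[i, ]),
      v = lapply(seq_len(nc), function(j) lev[, j]),
      d1 = {  # top-left to bottom-right diagonals
        split(as.vector(lev), as.vector(col(lev) - row(lev)))
      },
      d2 = {  # bottom-left to top-right diagonals
        split(as.vector(lev), as.vector(col(lev) + row(lev)))
      })
  }
  lapply(c("h", "v", "d1", "d2"), function(dir) {
    M <- matrix(0, d$ng, max_run)
    for (line in lines_for(dir)) {
      rl <- rle(as.integer(line))
      keep <- rl$values > 0
      if (any(keep))
        for (k in which(keep))
          M[rl$values[k], rl$lengths[k]] <- M[rl$values[k], rl$lengths[k]] + 1
    }
    # trim trailing all-zero run-length columns (no effect on features)
    last <- max(c(1, which(colSums(M) > 0)))
    M[, seq_len(last), drop = FALSE]
  })
}

#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of equal gray level inside the mask; the
#' matrix `Z(g, s)` counts zones of level `g` and size `s`. With
#' `Nz = sum(Z)`, `p = Z / Nz`: `SmallAreaEmphasis = sum(p / s^2)`,
#' `LargeAreaEmphasis = sum(p s^2)`, `SizeZoneNonUniformity =
#' sum_s (sum_g Z)^2 / Nz`, `SmallAreaHighGrayLevelEmphasis =
#' sum(p g^2 / s^2)`, `GrayLevelVariance` = variance of `g` under the
#' zone-weighted marginal, `ZonePercentage = Nz / Np`.
#'
#' @inheritParams glcm_features
#' @export
glszm_features <- function(d) {
  Z <- glszm_matrix(d)
  np <- sum(d$mask)
  nz <- sum(Z)
  g <- row(Z); s <- col(Z)
  p <- Z / nz
  mu_g <- sum(g * p)
  c(SmallAreaEmphasis = sum(p / s^2),
    LargeAreaEmphasis = sum(p * s^2),
    SizeZoneNonUniformity = sum(colSums(Z)^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(p * g^2 / s^2),
    GrayLevelVariance = sum((g - mu_g)^2 * p),
    ZonePercentage = nz / np)
}

#' @rdname glszm_features
#' @return `glszm_matrix()` returns the zone-count matrix (gray level x size).
#' @export
glszm_matrix <- function(d) {
  if (sum(d$mask) == 0) stop("empty ROI", call. = FALSE)
  sizes <- integer(0); glevels <- integer(0)
  for (g in seq_len(d$ng)) {
    sel <- d$levels == g
    if (!any(sel)) next
    lab <- .label_components(sel)
    if (max(lab) > 0) {
      zs <- tabulate(lab[lab > 0])
      sizes <- c(sizes, zs)
      glevels <- c(glevels, rep(g, length(zs)))
    }
  }
  M <- matrix(0, d$ng, max(sizes))
  for (k in seq_along(sizes))
    M[glevels[k], sizes[k]] <- M[glevels[k], sizes[k]] + 1
  M
}

#' Gray-level dependence matrix features
#'
#' The dependence count of a foreground pixel is the number of its 8-neighbors
#' inside the mask whose level differs by at most alpha = 0 (exact match).
#' The matrix `D(g, d)` counts pixels of level `g` with dependence index
#' `d = count + 1`. With `Np = sum(D)` (the foreground pixel count) and
#' `p = D / Np`: `SmallDependenceEmphasis = sum(p / d^2)`,
#' `LargeDependenceEmphasis = sum(p d^2)`, `DependenceNonUniformity =
#' sum_d (sum_g D)^2 / Np`, `SmallDependenceHighGrayLevelEmphasis =
#' sum(p g^2 / d^2)`, `GrayLevelNonUniformity = sum_g (sum_d D)^2 / Np`.
#'
#' @inheritParams glcm_features
#' @export
gldm_features <- function(d) {
  D <- gldm_matrix(d)
  np <- sum(D)
  g <- row(D); dd <- col(D)
  p <- D / np
  c(SmallDependenceEmphasis = sum(p / dd^2),
    LargeDependenceEmphasis = sum(p * dd^2),
    DependenceNonUniformity = sum(colSums(D)^2) / np,
    SmallDependenceHighGrayLevelEmphasis = sum(p * g^2 / dd^2),
    GrayLevelNonUniformity = sum(rowSums(D)^2) / np)
}

#' @rdname gldm_features
#' @return `gldm_matrix()` returns the dependence-count matrix
#'   (gray level x dependence index, where index = dependence count + 1).
#' @export
gldm_matrix <- function(d) {
  if (sum(d$mask) == 0) stop("empty ROI", call. = FALSE)
  lev <- d$levels
  dep <- matrix(0L, nrow(lev), ncol(lev))
  for (dd in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
                  c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    sh <- .shift_levels(lev, dd[1], dd[2])
    dep <- dep + (lev > 0 & sh > 0 & sh == lev)
  }
  fg <- which(lev > 0)
  max_d <- max(dep[fg]) + 1L
  M <- matrix(0, d$ng, max_d)
  tab <- table(factor(lev[fg], levels = 1:d$ng),
               factor(dep[fg] + 1L, levels = 1:max_d))
  M[] <- unclass(tab)
  M
}

#' Neighborhood gray-tone difference matrix features
#'
#' For each occupied level `i`, `s_i` is the sum over foreground pixels of
#' level `i` (having at least one valid in-mask 8-neighbor) of the absolute
#' difference between `i` and the mean level of those neighbors; `p_i` is the
#' fraction of such pixels at level `i` (`Nvp` pixels in total). Features:
#' \itemize{
#'   \item `Coarseness = 1 / sum(p_i s_i)`, capped at 1e6 when the
#'     denominator is 0 (e.g. a constant ROI).
#'   \item `Contrast = (sum_{i != j} p_i p_j (i - j)^2 / (Ngp (Ngp - 1)))
#'     * (sum_i s_i / Nvp)` with `Ngp` the number of occupied levels; 0 when
#'     `Ngp = 1`.
#'   \item `Complexity = (1 / Nvp) * sum_{i, j} |i - j| (p_i s_i + p_j s_j)
#'     / (p_i + p_j)` over occupied level pairs.
#' }
#'
#' @inheritParams glcm_features
#' @export
ngtdm_features <- function(d) {
  tab <- ngtdm_table(d)
  p <- tab$p; s <- tab$s
  occ <- which(p > 0)
  ngp <- length(occ)
  nvp <- tab$nvp
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  contrast <- 0; complexity <- 0
  if (ngp > 1) {
    ii <- rep(occ, each = ngp); jj <- rep(occ, times = ngp)
    contrast <- sum(p[ii] * p[jj] * (ii - jj)^2) / (ngp * (ngp - 1)) *
      sum(s) / nvp
    complexity <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                        (p[ii] + p[jj])) / nvp
  }
  c(Coarseness = coarseness, Contrast = contrast, Complexity = complexity)
}

#' @rdname ngtdm_features
#' @return `ngtdm_table()` returns a list with level probabilities `p`,
#'   absolute-difference sums `s`, and the count `nvp` of valid pixels.
#' @export
ngtdm_table <- function(d) {
  if (sum(d$mask) == 0) stop("empty ROI", call. = FALSE)
  lev <- d$levels
  nb_sum <- matrix(0, nrow(lev), ncol(lev))
  nb_cnt <- matrix(0L, nrow(lev), ncol(lev))
  for (dd in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
                  c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    sh <- .shift_levels(lev, dd[1], dd[2])
    nb_sum <- nb_sum + sh
    nb_cnt <- nb_cnt + (sh > 0L)
  }
  valid <- lev > 0 & nb_cnt > 0
  nvp <- sum(valid)
  diffs <- abs(lev[valid] - nb_sum[valid] / nb_cnt[valid])
  lv <- lev[valid]
  s <- vapply(seq_len(d$ng), function(g) sum(diffs[lv == g]), numeric(1))
  n_i <- vapply(seq_len(d$ng), function(g) sum(lv == g), numeric(1))
  list(p = n_i / nvp, s = s, nvp = nvp)
}
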