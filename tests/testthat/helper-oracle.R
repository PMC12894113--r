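# Independent brute-force oracles for the texture-matrix families.
# Matrices are built by explicit per-pixel enumeration (no vectorized
# shifting, no shared code with the implementation) and features by naive
# loops over matrix cells.

.oracle_dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))

.in_grid <- function(r, c, nr, nc) r >= 1 && r <= nr && c >= 1 && c <= nc

oracle_glcm <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev); ng <- max(lev)
  per_dir <- sapply(.oracle_dirs, function(d) {
    M <- matrix(0, ng, ng)
    for (r in 1:nr) for (c in 1:nc) {
      if (lev[r, c] == 0) next
      r2 <- r + d[1]; c2 <- c + d[2]
      if (!.in_grid(r2, c2, nr, nc) || lev[r2, c2] == 0) next
      M[lev[r, c], lev[r2, c2]] <- M[lev[r, c], lev[r2, c2]] + 1
      M[lev[r2, c2], lev[r, c]] <- M[lev[r2, c2], lev[r, c]] + 1
    }
    if (sum(M) == 0) { M <- matrix(0, ng, ng); M[1, 1] <- 1 } else
      M <- M / sum(M)
    mu <- 0
    for (i in 1:ng) for (j in 1:ng) mu <- mu + i * M[i, j]
    ja <- mu; sa <- 0; ct <- 0; cp <- 0; je <- 0
    for (i in 1:ng) for (j in 1:ng) {
      p <- M[i, j]
      sa <- sa + (i + j) * p
      ct <- ct + (i - j)^2 * p
      cp <- cp + (i + j - 2 * mu)^4 * p
      if (p > 0) je <- je - p * log2(p)
    }
    c(JointAverage = ja, SumAverage = sa, Contrast = ct,
      ClusterProminence = cp, JointEntropy = je)
  })
  rowMeans(per_dir)
}

# runs by explicit walking along every line of a direction
.oracle_runs <- function(lev, d) {
  nr <- nrow(lev); nc <- ncol(lev)
  runs <- list()
  starts <- which(matrix(TRUE, nr, nc), arr.ind = TRUE)
  # line starts: cells with no predecessor in direction d
  for (k in seq_len(nrow(starts))) {
    r <- starts[k, 1]; c <- starts[k, 2]
    if (.in_grid(r - d[1], c - d[2], nr, nc)) next
    # walk the line
    vals <- integer(0)
    while (.in_grid(r, c, nr, nc)) {
      vals <- c(vals, lev[r, c])
      r <- r + d[1]; c <- c + d[2]
    }
    i <- 1
    while (i <= length(vals)) {
      if (vals[i] > 0) {
        j <- i
        while (j < length(vals) && vals[j + 1] == vals[i]) j <- j + 1
        runs[[length(runs) + 1]] <- c(vals[i], j - i + 1)
        i <- j + 1
      } else i <- i + 1
    }
  }
  runs
}

oracle_glrlm <- function(lev) {
  np <- sum(lev > 0)
  per_dir <- sapply(.oracle_dirs, function(d) {
    runs <- .oracle_runs(lev, d)
    nr_runs <- length(runs)
    sre <- lre <- srhgle <- glv <- 0
    mu <- 0
    for (rn in runs) mu <- mu + rn[1] / nr_runs
    gl_tab <- list(); rl_tab <- list()
    for (rn in runs) {
      g <- rn[1]; l <- rn[2]
      sre <- sre + 1 / l^2 / nr_runs
      lre <- lre + l^2 / nr_runs
      srhgle <- srhgle + g^2 / l^2 / nr_runs
      glv <- glv + (g - mu)^2 / nr_runs
      gl_tab[[as.character(g)]] <- c(gl_tab[[as.character(g)]], 1)
      rl_tab[[as.character(l)]] <- c(rl_tab[[as.character(l)]], 1)
    }
    gln <- sum(sapply(gl_tab, sum)^2) / nr_runs
    rln <- sum(sapply(rl_tab, sum)^2) / nr_runs
    c(ShortRunEmphasis = sre, LongRunEmphasis = lre,
      GrayLevelNonUniformity = gln, RunLengthNonUniformity = rln,
      ShortRunHighGrayLevelEmphasis = srhgle, GrayLevelVariance = glv,
      RunPercentage = nr_runs / np)
  })
  rowMeans(per_dir)
}

# zone labeling by repeated label propagation to a fixed point (distinct
# algorithm from the implementation's BFS)
oracle_zones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[lev == 0] <- 0
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (lev[r, c] == 0) next
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if ((dr | dc) && .in_grid(r2, c2, nr, nc) &&
            lev[r2, c2] == lev[r, c] && lab[r2, c2] < lab[r, c]) {
          lab[r, c] <- lab[r2, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  zones <- list()
  for (id in unique(lab[lab > 0]))
    zones[[length(zones) + 1]] <- c(lev[lab == id][1], sum(lab == id))
  zones
}

oracle_glszm <- function(lev) {
  zones <- oracle_zones(lev)
  np <- sum(lev > 0); nz <- length(zones)
  sae <- lae <- sahgle <- glv <- 0
  mu <- 0
  for (z in zones) mu <- mu + z[1] / nz
  sz_tab <- list()
  for (z in zones) {
    g <- z[1]; s <- z[2]
    sae <- sae + 1 / s^2 / nz
    lae <- lae + s^2 / nz
    sahgle <- sahgle + g^2 / s^2 / nz
    glv <- glv + (g - mu)^2 / nz
    sz_tab[[as.character(s)]] <- c(sz_tab[[as.character(s)]], 1)
  }
  szn <- sum(sapply(sz_tab, sum)^2) / nz
  c(SmallAreaEmphasis = sae, LargeAreaEmphasis = lae,
    SizeZoneNonUniformity = szn, SmallAreaHighGrayLevelEmphasis = sahgle,
    GrayLevelVariance = glv, ZonePercentage = nz / np)
}

oracle_gldm <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  deps <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (lev[r, c] == 0) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (.in_grid(r2, c2, nr, nc) && lev[r2, c2] == lev[r, c]) dep <- dep + 1
    }
    deps[[length(deps) + 1]] <- c(lev[r, c], dep + 1)
  }
  np <- length(deps)
  sde <- lde <- sdhgle <- 0
  g_tab <- list(); d_tab <- list()
  for (x in deps) {
    g <- x[1]; d <- x[2]
    sde <- sde + 1 / d^2 / np
    lde <- lde + d^2 / np
    sdhgle <- sdhgle + g^2 / d^2 / np
    g_tab[[as.character(g)]] <- c(g_tab[[as.character(g)]], 1)
    d_tab[[as.character(d)]] <- c(d_tab[[as.character(d)]], 1)
  }
  dn <- sum(sapply(d_tab, sum)^2) / np
  gln <- sum(sapply(g_tab, sum)^2) / np
  c(SmallDependenceEmphasis = sde, LargeDependenceEmphasis = lde,
    DependenceNonUniformity = dn,
    SmallDependenceHighGrayLevelEmphasis = sdhgle,
    GrayLevelNonUniformity = gln)
}

oracle_ngtdm <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev); ng <- max(lev)
  s <- rep(0, ng); n_i <- rep(0, ng); nvp <- 0
  for (r in 1:nr) for (c in 1:nc) {
    if (lev[r, c] == 0) next
    tot <- 0; cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (.in_grid(r2, c2, nr, nc) && lev[r2, c2] > 0) {
        tot <- tot + lev[r2, c2]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) {
      g <- lev[r, c]
      nvp <- nvp + 1
      n_i[g] <- n_i[g] + 1
      s[g] <- s[g] + abs(g - tot / cnt)
    }
  }
  p <- n_i / nvp
  occ <- which(p > 0); ngp <- length(occ)
  den <- 0
  for (i in occ) den <- den + p[i] * s[i]
  coarseness <- if (den > 0) min(1 / den, 1e6) else 1e6
  contrast <- 0; complexity <- 0
  if (ngp > 1) {
    for (i in occ) for (j in occ) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      complexity <- complexity +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nvp
    complexity <- complexity / nvp
  }
  c(Coarseness = coarseness, Contrast = contrast, Complexity = complexity)
}
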