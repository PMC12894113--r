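#' Synthetic-cohort generator configuration
#'
#' Defines the study conditions emulated by the generator: marginal means and
#' SDs of the clinical variables, the linear generative link from predictors
#' to final height (sign pattern: height at menarche +, father's height +,
#' hand-wrist bone age -, imaging latent +), the ~2 cm residual scale, and
#' the latent channel through which image texture and the femur radiomic
#' score carry true height signal. The tibia score is decoupled from final
#' height (pure noise), emulating a null imaging site.
#'
#' Two independent standard-normal latents shape each subject: a *skeletal
#' maturity* latent that drives the bone-age readings (an advanced bone age
#' at menarche means less remaining growth, hence the negative bone-age
#' coefficient), and a *growth reserve* latent `m` that the femur epiphysis
#' texture encodes and that adds final height beyond what bone age explains
#' (the positive `beta["maturity"]` term). Separating the two reproduces the
#' empirical pattern that the bone age correlates negatively and the femur
#' score positively with final height.
#'
#' The femur score is a noisy affine transform of `m`; its noise
#' (`score_noise_sd` = 0.25) is calibrated so the score's marginal R-squared
#' with final height is about 0.19 under the default conditions. Bone-age
#' readings match the target marginal SDs (a weighted combination of the age
#' z-score and the maturity latent plus per-reader noise of SD 0.25 y); the
#' knee-atlas readers carry opposite systematic offsets of 0.15 y,
#' reproducing a between-reader bias, and the knee atlas has an
#' atlas-specific variance component of its own.
#'
#' @param n_subjects cohort size (>= 20; default 173).
#' @param seed integer master seed; all cohort randomness derives from it.
#' @param means,sds named numeric vectors of marginal targets
#'   (`age_menarche`, `height_menarche`, `father_height`, `mother_height`,
#'   `ba_gp`, `ba_ph`, `final_height`).
#' @param beta generative coefficients: intercept, `height_menarche`,
#'   `father_height`, `ba_gp_mean`, and `maturity` (the coefficient on the
#'   growth-reserve latent `m`).
#' @param residual_sd residual SD of final height about the linear model, cm
#'   (default 2.0).
#' @param score_center,score_scale,score_noise_sd femur-score transform
#'   `center + scale * (m + e) / sqrt(1 + sd^2)`, `e ~ N(0, sd^2)`.
#' @param texture_effect strength of the latent-maturity to image-texture
#'   link (default 1; 0 ablates the texture channel).
#' @param observer_jitter SD, in pixels, of simulated delineation jitter
#'   (default 2).
#' @param image_size side of the square synthetic radiograph (default 256).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 173, seed = 1,
                             means = c(age_menarche = 11.01,
                                       height_menarche = 150.62,
                                       father_height = 172.34,
                                       mother_height = 159.10,
                                       ba_gp = 12.35, ba_ph = 12.76,
                                       final_height = 159.56),
                             sds = c(age_menarche = 0.98,
                                     height_menarche = 4.28,
                                     father_height = 5.46,
                                     mother_height = 5.30,
                                     ba_gp = 0.79, ba_ph = 0.58,
                                     final_height = 3.81),
                             beta = c(intercept = NA, height_menarche = 0.70,
                                      father_height = 0.15,
                                      ba_gp_mean = -1.91, maturity = 0.80),
                             residual_sd = 2.0,
                             score_center = 5.0, score_scale = 0.5,
                             score_noise_sd = 0.25,
                             texture_effect = 1, observer_jitter = 2,
                             image_size = 256) {
  if (n_subjects < 20) stop("n_subjects must be at least 20", call. = FALSE)
  if (residual_sd <= 0) stop("residual_sd must be positive", call. = FALSE)
  if (is.na(beta["intercept"]))  # center final height on its target mean
    beta["intercept"] <- means[["final_height"]] -
      beta[["height_menarche"]] * means[["height_menarche"]] -
      beta[["father_height"]] * means[["father_height"]] -
      beta[["ba_gp_mean"]] * means[["ba_gp"]]
  cfg <- list(n_subjects = n_subjects, seed = seed, means = means, sds = sds,
              beta = beta, residual_sd = residual_sd,
              score_center = score_center, score_scale = score_scale,
              score_noise_sd = score_noise_sd,
              texture_effect = texture_effect,
              observer_jitter = observer_jitter, image_size = image_size)
  class(cfg) <- "generator_config"
  cfg
}

# Correlation structure among (height_menarche, father, mother, skeletal
# maturity, growth-reserve latent): modest positive correlations among the
# anthropometric variables, a maturity-stature link (advanced maturers are
# taller at menarche), and a stature link for the growth-reserve latent that
# the femur texture encodes. The two latents are independent of each other:
# maturity acts on final height through bone age (negatively), the growth
# reserve acts directly (positively).
.CLIN_CORR <- matrix(c(
  1.00, 0.30, 0.30, 0.30, 0.35,
  0.30, 1.00, 0.20, 0.00, 0.00,
  0.30, 0.20, 1.00, 0.00, 0.00,
  0.30, 0.00, 0.00, 1.00, 0.00,
  0.35, 0.00, 0.00, 0.00, 1.00), 5, 5,
  dimnames = rep(list(c("hm", "fa", "mo", "mat", "g")), 2))

# derive a reproducible sub-seed from the master seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Generate a synthetic clinical cohort
#'
#' Draws correlated (height at menarche, parental heights, skeletal
#' maturity, growth reserve), bone-age readings for two readers per atlas,
#' radiomic-score proxies, and final heights from the generative linear
#' model `final = b0 + b1 * height_menarche + b2 * father + b3 * ba_gp_mean
#' + b4 * m + e`, `e ~ N(0, residual_sd^2)`, with `m` the growth-reserve
#' latent (see [generator_config()]).
#'
#' @param config a [generator_config()].
#' @return List with `clinical` (data.frame in the [read_clinical_csv()]
#'   schema plus mean-BA columns), `truth` (data.frame: `m`, `maturity`,
#'   `femur_score`, `tibia_score`, `noise`), and `beta` (the generative
#'   coefficients).
#' @export
generate_clinical <- function(config = generator_config()) {
  ev <- eigen(.CLIN_CORR, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("infeasible correlation matrix", call. = FALSE)
  set.seed(derive_seed(config$seed, "clinical"))
  n <- config$n_subjects
  mu <- config$means; sdv <- config$sds
  z <- matrix(rnorm(n * 5), n, 5) %*%
    (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
  hm <- mu[["height_menarche"]] + sdv[["height_menarche"]] * z[, 1]
  fa <- mu[["father_height"]] + sdv[["father_height"]] * z[, 2]
  mo <- mu[["mother_height"]] + sdv[["mother_height"]] * z[, 3]
  mat <- z[, 4]  # skeletal maturity: drives bone age
  g <- z[, 5]    # growth reserve: drives femur texture and final height
  age <- mu[["age_menarche"]] + sdv[["age_menarche"]] * rnorm(n)
  za <- (age - mu[["age_menarche"]]) / sdv[["age_menarche"]]
  # bone-age structure: BA = target mean + c_a * z(age) + c_m * maturity +
  # reader noise; weights chosen to land the mean-of-readers SD on target
  ba_gp_true <- mu[["ba_gp"]] + 0.45 * za + 0.55 * mat
  # the knee atlas tracks the same maturation more loosely and carries an
  # atlas/site-specific component of its own
  ba_ph_true <- mu[["ba_ph"]] + 0.30 * za + 0.25 * mat + rnorm(n, 0, 0.39)
  reader_sd <- 0.25
  ba_gp1 <- ba_gp_true + rnorm(n, 0, reader_sd)
  ba_gp2 <- ba_gp_true + rnorm(n, 0, reader_sd)
  ba_ph1 <- ba_ph_true + 0.15 + rnorm(n, 0, reader_sd)
  ba_ph2 <- ba_ph_true - 0.15 + rnorm(n, 0, reader_sd)
  ba_gp_mean <- (ba_gp1 + ba_gp2) / 2
  b <- config$beta
  noise <- rnorm(n, 0, config$residual_sd)
  final <- b[["intercept"]] + b[["height_menarche"]] * hm +
    b[["father_height"]] * fa + b[["ba_gp_mean"]] * ba_gp_mean +
    b[["maturity"]] * g + noise
  tau <- config$score_noise_sd
  femur_score <- config$score_center + config$score_scale *
    (g + rnorm(n, 0, tau)) / sqrt(1 + tau^2)
  tibia_score <- config$score_center + config$score_scale * rnorm(n)
  clinical <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age_menarche = round(age, 2),
    height_menarche = hm, father_height = fa, mother_height = mo,
    ba_gp_reader1 = ba_gp1, ba_gp_reader2 = ba_gp2,
    ba_ph_reader1 = ba_ph1, ba_ph_reader2 = ba_ph2,
    final_height = final, stringsAsFactors = FALSE)
  clinical$ba_gp_mean <- (clinical$ba_gp_reader1 + clinical$ba_gp_reader2) / 2
  clinical$ba_ph_mean <- (clinical$ba_ph_reader1 + clinical$ba_ph_reader2) / 2
  list(clinical = clinical,
       truth = data.frame(subject_id = clinical$subject_id, m = g,
                          maturity = mat, femur_score = femur_score,
                          tibia_score = tibia_score, noise = noise,
                          stringsAsFactors = FALSE),
       beta = b)
}

# smooth correlated speckle: white noise box-blurred a few times
.speckle <- function(size, passes = 2) {
  x <- matrix(rnorm(size * size), size, size)
  for (i in seq_len(passes)) {
    x <- (x +
      .shift_num(x, 1, 0) + .shift_num(x, -1, 0) +
      .shift_num(x, 0, 1) + .shift_num(x, 0, -1)) / 5
  }
  x / sd(x)
}

.shift_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r0 <- max(1, 1 + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1, 1 + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(out)
  out[(r0:r1) - dr, (c0:c1) - dc] <- m[r0:r1, c0:c1]
  out
}

#' Render a procedural knee-epiphysis image
#'
#' Produces a synthetic grayscale radiograph patch: an elliptical epiphysis
#' and a metaphysis block separated by a dark physis band whose width shrinks
#' as latent maturity `m` grows, plus in-bone speckle texture whose contrast
#' increases with `m * texture_effect`, and additive Gaussian noise. The true
#' ROI is a 24-vertex polygon on the epiphysis ellipse. This is a texture
#' phantom, not an anatomically realistic radiograph.
#'
#' @param m latent maturity (standard-normal scale).
#' @param site `"distal_femur"` (epiphysis above the physis) or
#'   `"proximal_tibia"` (below).
#' @param config a [generator_config()] (uses `image_size` and
#'   `texture_effect`).
#' @param seed integer seed; the same `(m, site, seed)` reproduces the image
#'   bit for bit.
#' @return List with `image` (matrix, intensities 0-255) and `polygon`
#'   (24 x 2 matrix of `(x, y)` vertices).
#' @export
render_epiphysis_image <- function(m, site = "distal_femur",
                                   config = generator_config(), seed = 1) {
  site <- match.arg(site, ROI_SITES)
  stopifnot(is.finite(m))
  set.seed(derive_seed(seed, paste0("render_", site)))
  sz <- config$image_size
  img <- matrix(55, sz, sz) + 2 * matrix(rnorm(sz * sz), sz, sz)  # soft tissue
  cx <- sz / 2 + runif(1, -4, 4)
  physis_y <- sz / 2 + runif(1, -6, 6)
  band_w <- max(2, 7 - 3 * tanh(m))  # physis narrows with maturity
  # per-subject anatomy: epiphysis size varies between subjects so that
  # shape features are subject-discriminative (as in a real cohort)
  size_scale <- runif(1, 0.85, 1.15)
  a <- sz * 0.30 * size_scale; bsh <- sz * 0.14 * size_scale
  cy <- if (site == "distal_femur") physis_y - band_w / 2 - bsh * 1.05
        else physis_y + band_w / 2 + bsh * 1.05
  xg <- matrix(rep(seq_len(sz) - 1, each = sz), sz, sz)   # x = col - 1
  yg <- matrix(rep(seq_len(sz) - 1, times = sz), sz, sz)  # y = row - 1
  in_epi <- ((xg - cx) / a)^2 + ((yg - cy) / bsh)^2 <= 1
  meta_y0 <- if (site == "distal_femur") physis_y + band_w / 2
             else 0
  meta_y1 <- if (site == "distal_femur") sz - 1 else physis_y - band_w / 2
  in_meta <- abs(xg - cx) <= a * 0.85 & yg >= meta_y0 & yg <= meta_y1
  contrast <- 10 * (1 + config$texture_effect * stats::pnorm(m))
  tex <- .speckle(sz)
  img[in_meta] <- 150 + 8 * tex[in_meta]
  img[in_epi] <- 170 + contrast * tex[in_epi]
  in_band <- abs(yg - physis_y) <= band_w / 2 & abs(xg - cx) <= a
  img[in_band] <- 90 + 3 * tex[in_band]
  img <- img + 3 * matrix(rnorm(sz * sz), sz, sz)
  img <- pmin(pmax(img, 0), 255)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  polygon <- cbind(x = cx + 0.9 * a * cos(th), y = cy + 0.9 * bsh * sin(th))
  list(image = img, polygon = polygon)
}

# TRUE iff the closed polygon has no self-intersections between
# non-adjacent edges
.is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closure
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Jitter a polygon annotation
#'
#' Simulates observer delineation variability by adding independent Gaussian
#' displacements (SD = `jitter_px`) to every vertex, rejecting candidates
#' that self-intersect (up to 100 redraws).
#'
#' @param polygon n x 2 vertex matrix.
#' @param jitter_px displacement SD in pixels; 0 returns the polygon
#'   unchanged.
#' @param seed integer seed.
#' @return Jittered n x 2 vertex matrix.
#' @export
jitter_annotation <- function(polygon, jitter_px, seed = 1) {
  if (jitter_px == 0) return(polygon)
  set.seed(derive_seed(seed, "jitter"))
  for (try in 1:100) {
    cand <- polygon + matrix(rnorm(length(polygon), 0, jitter_px),
                             nrow(polygon), 2)
    if (.is_simple_polygon(cand)) {
      colnames(cand) <- c("x", "y")
      return(cand)
    }
  }
  stop("jitter error: no simple polygon in 100 tries", call. = FALSE)
}

#' Generate and write a complete synthetic cohort
#'
#' Writes the full on-disk layout consumed by the pipeline:
#' `images/<subject>_<site>.png`, labelme-style annotations
#' `annotations/<subject>_<site>_<observer>[_repeat].json` (observer 2 covers
#' the first `min(n, 60)` subjects, the repeat session of observer 1 the
#' first `min(n, 100)` — the inter- and intra-observer reliability subsets),
#' `clinical.csv`, and `ground_truth.json` holding the generative parameters
#' and latent values.
#'
#' @param config a [generator_config()].
#' @param dir target directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param force overwrite a non-empty directory.
#' @param write_images set `FALSE` to skip image/annotation rendering (for
#'   clinical-only studies).
#' @return Invisibly, a list with the cohort (`clinical`, `truth`, `beta`)
#'   and `dir`.
#' @export
generate_cohort <- function(config = generator_config(), dir,
                            force = FALSE, write_images = TRUE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("target directory is non-empty; use force = TRUE", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coh <- generate_clinical(config)
  write_clinical_csv(coh$clinical, file.path(dir, "clinical.csv"))
  jsonlite::write_json(
    list(seed = config$seed, beta = as.list(coh$beta),
         residual_sd = config$residual_sd,
         score = list(center = config$score_center,
                      scale = config$score_scale,
                      noise_sd = config$score_noise_sd),
         texture_effect = config$texture_effect,
         observer_jitter = config$observer_jitter,
         truth = coh$truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  if (write_images) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
    n <- config$n_subjects
    n_inter <- min(n, 60); n_intra <- min(n, 100)
    for (i in seq_len(n)) {
      sid <- coh$clinical$subject_id[i]
      for (site in ROI_SITES) {
        # the tibia texture channel is decoupled from final height: its
        # rendering maturity is an independent draw, not the latent m
        m_img <- if (site == "distal_femur") coh$truth$m[i] else
          local({set.seed(derive_seed(config$seed, paste0("tibia_m_", i)))
                 rnorm(1)})
        rend <- render_epiphysis_image(m_img, site, config,
                                       seed = derive_seed(config$seed,
                                                          paste0(sid, site)))
        write_gray_image(rend$image,
                         file.path(dir, "images",
                                   paste0(sid, "_", site, ".png")))
        shp <- dim(rend$image)
        write_ann <- function(poly, tag) {
          polys <- setNames(list(poly), site)
          write_labelme_annotation(
            polys, file.path(dir, "annotations",
                             paste0(sid, "_", site, "_", tag, ".json")), shp)
        }
        j <- function(tag_seed) jitter_annotation(
          rend$polygon, config$observer_jitter,
          seed = derive_seed(config$seed, paste0(sid, site, tag_seed)))
        write_ann(j("obs1"), "obs1")
        if (i <= n_inter) write_ann(j("obs2"), "obs2")
        if (i <= n_intra) write_ann(j("obs1r"), "obs1_repeat")
      }
    }
  }
  invisible(c(coh, list(dir = dir)))
}
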