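# Shared fixture builders (everything is generated in code).

# discretized ROI straight from an integer level matrix (0 = background)
droi <- function(levels) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  structure(list(levels = levels, ng = max(levels),
                 bin_edges = seq(0, max(levels)),
                 mask = levels > 0),
            class = "discretized_roi")
}

# random discretized ROI: nr x nc grid, levels 1..ng, irregular mask
random_droi <- function(nr = 6, nc = 6, ng = 4, p_mask = 0.8) {
  repeat {
    mask <- matrix(runif(nr * nc) < p_mask, nr, nc)
    if (sum(mask) >= 4) break
  }
  lev <- matrix(0L, nr, nc)
  lev[mask] <- sample.int(ng, sum(mask), replace = TRUE)
  droi(lev)
}

# ROI image with at least 16 foreground pixels from a value matrix
roi_from <- function(values, mask = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(1, nrow(values), ncol(values))
  roi_image(values, mask, ...)
}

# small rendered femur ROI for integration-style tests
rendered_roi <- function(m = 0.5, seed = 1, image_size = 128,
                         site = "distal_femur") {
  cfg <- generator_config(image_size = image_size)
  r <- render_epiphysis_image(m, site, cfg, seed = seed)
  mask <- rasterize_polygon(r$polygon, dim(r$image))
  roi_image(r$image, mask, site = site)
}
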