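#' First-order (histogram) features
#'
#' Computes intensity-distribution features on the raw (non-discretized)
#' foreground intensities of an ROI. Conventions, stated at the definition
#' site: `Variance` uses the N denominator (population variance);
#' percentiles and the interquartile range use linear interpolation
#' (R quantile type 7); `RobustMeanAbsoluteDeviation` is the mean absolute
#' deviation, from their own mean, of the values lying within the 10th-90th
#' percentile range (inclusive).
#'
#' @param roi an [roi_image()].
#' @return Named numeric vector of features.
#' @export
firstorder_features <- function(roi) {
  x <- roi$pixels[roi$mask]
  if (length(x) == 0) stop("empty ROI", call. = FALSE)
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  c(Mean = mean(x),
    Median = median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = mean((x - mean(x))^2),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2],
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))))
}

#' 2D shape features of a mask
#'
#' Shape descriptors of the foreground region (the largest 8-connected
#' component is used if the mask is disconnected):
#' \itemize{
#'   \item `MajorAxisLength`, `MinorAxisLength`: `4 * sqrt(lambda)` for the
#'     largest/smallest eigenvalue of the sample covariance (denominator
#'     n - 1) of the foreground pixel-center coordinates.
#'   \item `MaximumDiameter`: largest pairwise Euclidean distance between
#'     boundary pixel centers.
#'   \item `Perimeter`: length of the crack (pixel-edge) boundary contour,
#'     i.e. the count of foreground pixel edges facing background. This is
#'     the unsmoothed convention; smoothed-mesh perimeters run shorter.
#'   \item `PixelSurface`: foreground pixel count (area in pixel units).
#' }
#' All quantities are in pixel units; physical spacing is not applied.
#'
#' @param mask binary matrix.
#' @return Named numeric vector of features.
#' @export
shape2d_features <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (sum(mask) == 0) stop("empty ROI", call. = FALSE)
  comp <- .largest_component(mask == 1)
  idx <- which(comp, arr.ind = TRUE)
  n <- nrow(idx)
  # coordinates of pixel centers: x = col - 1, y = row - 1
  coords <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  if (n > 1) {
    ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[length(ev)])
  } else major <- minor <- 0
  # boundary pixels: foreground with at least one 4-neighbor outside the region
  pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  core <- pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)]
  nb4 <- pad[1:nrow(comp), 2:(ncol(comp) + 1)] +
    pad[3:(nrow(comp) + 2), 2:(ncol(comp) + 1)] +
    pad[2:(nrow(comp) + 1), 1:ncol(comp)] +
    pad[2:(nrow(comp) + 1), 3:(ncol(comp) + 2)]
  boundary <- core & nb4 < 4
  perimeter <- sum(core * (4 - nb4))
  bidx <- which(boundary, arr.ind = TRUE)
  bco <- cbind(bidx[, 2] - 1, bidx[, 1] - 1)
  maxdiam <- if (nrow(bco) > 1) sqrt(max(as.matrix(stats::dist(bco))^2)) else 0
  c(MajorAxisLength = major,
    MinorAxisLength = minor,
    MaximumDiameter = maxdiam,
    Perimeter = perimeter,
    PixelSurface = n)
}

# 8-connected components of a logical matrix by BFS; returns largest as logical
.largest_component <- function(mask) {
  lab <- .label_components(mask)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# 8-connected component labeling (BFS flood fill); returns integer label matrix
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  cur <- 0L
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  off_lin <- offs[, 1] + offs[, 2] * nr
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      r <- ((p - 1) %% nr) + 1
      for (k in seq_along(off_lin)) {
        # guard row wrap-around for the +-1 row offsets
        ok <- (r + offs[k, 1] >= 1) & (r + offs[k, 1] <= nr)
        q <- p[ok] + off_lin[k]
        q <- q[q >= 1 & q <= nr * nc]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}
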