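# Single-level stationary (undecimated) separable 2D wavelet filtering.
#
# The two bands used for texture extraction are the fully low-passed image
# ("L", approximation in both axes) and the fully high-passed image ("H",
# diagonal detail). The transform is shape-preserving (no downsampling) so the
# epiphyseal mask applies to the filtered image unchanged. Filters are
# normalized to unit DC gain: a constant image is preserved exactly by L and
# annihilated by H.

# Coiflet-1 decomposition filters, rescaled from the orthonormal coefficients
# (which sum to sqrt(2)) to unit DC gain.
.coif1_lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
               0.852572020212255, 0.337897662457809, -0.072732619512854) / sqrt(2)
.coif1_hi <- rev(.coif1_lo) * c(1, -1, 1, -1, 1, -1)

# periodic 1D convolution of each column of `m` with kernel `k`
.conv_cols <- function(m, k) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  # kernel taps centered: offset j shifts rows circularly
  half <- floor(length(k) / 2)
  for (j in seq_along(k)) {
    shift <- (j - 1 - half) %% n
    idx <- ((seq_len(n) - 1 + shift) %% n) + 1
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  out
}

#' Wavelet-filter an image
#'
#' Applies a single-level stationary separable 2D wavelet decomposition with a
#' Coiflet-1 kernel and periodic boundary handling. Band `"L"` low-passes both
#' axes (approximation); band `"H"` high-passes both axes (diagonal detail).
#' The output has the shape of the input, so ROI masks carry over unchanged.
#' Filters are normalized to unit DC gain: `wavelet_filter(c, "L")` returns
#' the constant `c` and `wavelet_filter(c, "H")` returns zero.
#'
#' @param image numeric matrix, at least 8 x 8.
#' @param band `"L"` or `"H"`.
#' @param wavelet kernel name; only `"coif1"` is provided.
#' @return Filtered numeric matrix of the same dimension.
#' @export
wavelet_filter <- function(image, band = c("L", "H"), wavelet = "coif1") {
  band <- match.arg(band)
  wavelet <- match.arg(wavelet, "coif1")
  image <- as.matrix(image)
  if (nrow(image) < 8 || ncol(image) < 8)
    stop("image must be at least 8 x 8 for the wavelet filter support",
         call. = FALSE)
  k <- if (band == "L") .coif1_lo else .coif1_hi
  t(.conv_cols(t(.conv_cols(image, k)), k))
}

#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width discretization of the foreground intensities:
#' `level(p) = floor((I(p) - min(I)) / bin_width) + 1`, so levels run 1..Ng
#' inside the mask and 0 outside. Adding a constant to all intensities leaves
#' the levels unchanged (the bin origin is the observed minimum), which makes
#' all downstream texture features gray-level-shift invariant.
#'
#' @param roi an [roi_image()].
#' @param bin_width positive bin width in intensity units. The default of 25
#'   is the common fixed-bin-width default for 8-bit radiograph exports.
#' @return List of class `discretized_roi`: `levels` (integer matrix),
#'   `ng` (number of levels), `bin_edges`, `mask`.
#' @export
discretize <- function(roi, bin_width = 25) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a positive number", call. = FALSE)
  if (sum(roi$mask) == 0) stop("empty ROI", call. = FALSE)
  vals <- roi$pixels[roi$mask]
  lo <- min(vals)
  lev <- matrix(0L, nrow(roi$pixels), ncol(roi$pixels))
  lev[roi$mask] <- as.integer(floor((vals - lo) / bin_width)) + 1L
  ng <- max(lev)
  structure(list(levels = lev, ng = ng,
                 bin_edges = lo + bin_width * seq(0, ng),
                 mask = roi$mask),
            class = "discretized_roi")
}
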