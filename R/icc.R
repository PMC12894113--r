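#' Intraclass correlation coefficients
#'
#' Single-measure ICCs from the two-way mean-squares decomposition of an
#' `n x k` ratings matrix (subjects x raters/sessions):
#' \itemize{
#'   \item `type = "ICC2"`: two-way random effects, absolute agreement,
#'     ICC(2,1) = `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'     A constant offset between raters counts against agreement.
#'   \item `type = "ICC3"`: two-way mixed effects, consistency,
#'     ICC(3,1) = `(MSR - MSE) / (MSR + (k-1) MSE)`. Insensitive to a
#'     constant offset.
#' }
#' `MSR`, `MSC`, `MSE` are the row (subject), column (rater) and residual
#' mean squares.
#'
#' @param ratings numeric matrix, n subjects (>= 5) by k >= 2 raters.
#' @param type `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @return ICC value in (-1, 1].
#' @export
icc_two_way <- function(ratings, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop("at least 5 subjects are required", call. = FALSE)
  if (k < 2) stop("at least 2 raters are required", call. = FALSE)
  grand <- mean(ratings)
  if (sum((ratings - grand)^2) == 0)
    stop("degenerate data: zero total variance", call. = FALSE)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC2")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Reliability gate over repeated feature extractions
#'
#' Screens radiomic features for delineation reproducibility. For every
#' feature, an inter-observer ICC(2,1) (absolute agreement between two
#' delineators) and an intra-observer ICC(3,1) (consistency of one delineator
#' across sessions) are computed; a feature passes iff both exceed the
#' threshold. The two designs follow the usual reliability practice:
#' absolute agreement across observers (a systematic delineation bias should
#' count against a feature), consistency within an observer.
#'
#' @param inter_a,inter_b feature matrices (subjects x features, identical
#'   dimnames) from the two observers on the inter-observer subset.
#' @param intra_a,intra_b feature matrices from the repeat sessions of one
#'   observer on the intra-observer subset.
#' @param threshold pass threshold for both ICCs (default 0.8, the customary
#'   "excellent stability" cut).
#' @return data.frame (one row per feature) with `icc_inter`, `icc_intra`,
#'   `pass`.
#' @export
stability_filter <- function(inter_a, inter_b, intra_a, intra_b,
                             threshold = 0.8) {
  .check_aligned <- function(a, b, what) {
    if (!identical(dim(a), dim(b)) ||
        !identical(rownames(a), rownames(b)) ||
        !identical(colnames(a), colnames(b)))
      stop("alignment error: ", what,
           " matrices must share subjects and features", call. = FALSE)
  }
  .check_aligned(inter_a, inter_b, "inter-observer")
  .check_aligned(intra_a, intra_b, "intra-observer")
  if (!identical(colnames(inter_a), colnames(intra_a)))
    stop("alignment error: inter- and intra-observer feature sets differ",
         call. = FALSE)
  feats <- colnames(inter_a)
  icc_of <- function(a, b, j, type) {
    tryCatch(icc_two_way(cbind(a[, j], b[, j]), type = type),
             error = function(e) NA_real_)
  }
  icc_inter <- vapply(feats, function(j) icc_of(inter_a, inter_b, j, "ICC2"),
                      numeric(1))
  icc_intra <- vapply(feats, function(j) icc_of(intra_a, intra_b, j, "ICC3"),
                      numeric(1))
  # a feature with degenerate (constant) ratings in either design:
  # identical columns => perfectly reproducible; otherwise it fails
  ident <- function(a, b) vapply(feats, function(j)
    isTRUE(all.equal(a[, j], b[, j], tolerance = 0)), logical(1))
  icc_inter[is.na(icc_inter) & ident(inter_a, inter_b)] <- 1
  icc_intra[is.na(icc_intra) & ident(intra_a, intra_b)] <- 1
  pass <- !is.na(icc_inter) & !is.na(icc_intra) &
    icc_inter > threshold & icc_intra > threshold
  data.frame(feature = feats, icc_inter = icc_inter, icc_intra = icc_intra,
             pass = pass, row.names = NULL, stringsAsFactors = FALSE)
}
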