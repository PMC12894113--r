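#' radheight: radiomic knee scores and final-height prediction
#'
#' Tools for predicting the adult height of girls at menarche from knee
#' radiographs and clinical covariates: 2D radiomic feature extraction over
#' annotated epiphyseal regions, a four-stage feature-reduction cascade
#' (ICC reliability, variance threshold, univariate screen, LASSO) yielding a
#' signed-log radiomic score, stepwise OLS prediction equations, Bayley-Pinneau
#' bone-age projection and mid-parental target height, and a cross-validated
#' evaluation battery (RMSE, RPD, residual buckets, Bland-Altman agreement).
#' A seeded synthetic-cohort generator makes every stage testable end to end.
#'
#' @importFrom stats AIC BIC coef confint cor lm median pchisq pf predict
#'   quantile rnorm runif sd setNames t.test var
#' @importFrom utils head read.csv write.csv
#' @keywords internal
"_PACKAGE"

# Anatomical sites used throughout the package.
ROI_SITES <- c("distal_femur", "proximal_tibia")

#' Construct an ROI image
#'
#' Bundles a grayscale pixel matrix with a same-shape binary epiphyseal mask.
#' Orientation follows the annotation-tool convention: matrices are indexed
#' `[row, col]` with the origin at the top-left; annotation coordinates are
#' `x` = column and `y` = row, both 0-based, and a pixel's center sits at
#' integer `(x, y)`.
#'
#' @param pixels numeric matrix of non-negative gray intensities.
#' @param mask binary matrix (0/1 or logical) of identical dimensions; at
#'   least 16 foreground pixels are required.
#' @param site `"distal_femur"` or `"proximal_tibia"`.
#' @param subject_id,observer_id opaque identifier strings.
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, mask, site = "distal_femur",
                      subject_id = "subject", observer_id = "obs1") {
  pixels <- as.matrix(pixels)
  if (is.logical(mask)) mask <- mask * 1L
  mask <- as.matrix(mask)
  if (!all(dim(pixels) == dim(mask)))
    stop("pixels and mask must have identical dimensions", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  if (sum(mask) < 16)
    stop("mask must contain at least 16 foreground pixels", call. = FALSE)
  site <- match.arg(site, ROI_SITES)
  structure(list(pixels = pixels, mask = mask == 1, site = site,
                 subject_id = subject_id, observer_id = observer_id),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %s / %s / %s: %d x %d, %d foreground px\n",
              x$subject_id, x$site, x$observer_id,
              nrow(x$pixels), ncol(x$pixels), sum(x$mask)))
  invisible(x)
}

#' Read a polygon annotation file
#'
#' Parses a labelme-dialect JSON annotation and returns one polygon per
#' anatomical site. Vertex coordinates are kept exactly as stored, in image
#' pixel units (x = column, y = row, 0-based).
#'
#' @param path path to the JSON file.
#' @param label_map named character vector mapping annotation label strings to
#'   sites; default maps `"femur"`/`"tibia"` (labelme label strings are not
#'   standardised, so the map is configurable).
#' @return A named list of polygons (n x 2 matrices with columns `x`, `y`),
#'   one per site present, in site order.
#' @export
read_labelme_annotation <- function(path,
                                    label_map = c(femur = "distal_femur",
                                                  tibia = "proximal_tibia")) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(ann$shapes))
    stop("not a labelme annotation: no 'shapes' field in ", path, call. = FALSE)
  out <- list()
  for (shape in ann$shapes) {
    lab <- shape$label
    if (is.null(lab) || !lab %in% names(label_map)) next
    site <- unname(label_map[[lab]])
    if (!is.null(shape$shape_type) && shape$shape_type != "polygon") next
    pts <- do.call(rbind, lapply(shape$points, function(p) as.numeric(p)))
    if (is.null(pts) || nrow(pts) < 3)
      stop("malformed annotation: polygon for site '", site,
           "' has fewer than 3 vertices", call. = FALSE)
    colnames(pts) <- c("x", "y")
    if (site %in% names(out))
      stop("duplicate site label '", site, "' in ", path, call. = FALSE)
    out[[site]] <- pts
  }
  if (length(out) == 0)
    stop("no labeled site found in ", path, call. = FALSE)
  out[order(match(names(out), ROI_SITES))]
}

#' Write a polygon annotation file
#'
#' Inverse of [read_labelme_annotation()]: serializes site polygons into a
#' labelme-dialect JSON.
#'
#' @param polygons named list of n x 2 vertex matrices keyed by site.
#' @param path output path.
#' @param image_shape integer `c(height, width)` recorded in the file.
#' @param label_map as in [read_labelme_annotation()].
#' @export
write_labelme_annotation <- function(polygons, path, image_shape,
                                     label_map = c(femur = "distal_femur",
                                                   tibia = "proximal_tibia")) {
  inv <- setNames(names(label_map), unname(label_map))
  shapes <- lapply(names(polygons), function(site) {
    pts <- polygons[[site]]
    list(label = unname(inv[[site]]),
         points = lapply(seq_len(nrow(pts)),
                         function(i) c(pts[i, 1], pts[i, 2])),
         shape_type = "polygon")
  })
  obj <- list(version = "5.4.1", shapes = shapes,
              imageHeight = image_shape[1], imageWidth = image_shape[2])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel `(r, c)` (0-based, center at x = c, y = r) is foreground iff its
#' center lies inside the polygon under the even-odd rule. Centers exactly on
#' an edge are resolved by the half-open crossing convention, which is
#' deterministic and consistent between runs.
#'
#' @param polygon n x 2 matrix of `(x, y)` vertices, n >= 3.
#' @param image_shape integer `c(height, width)`.
#' @return Integer 0/1 matrix of dimension `image_shape`.
#' @export
rasterize_polygon <- function(polygon, image_shape) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3)
    stop("polygon must have at least 3 vertices", call. = FALSE)
  h <- image_shape[1]; w <- image_shape[2]
  # restrict the test to the polygon's bounding box
  r0 <- max(0L, floor(min(polygon[, 2]))); r1 <- min(h - 1L, ceiling(max(polygon[, 2])))
  c0 <- max(0L, floor(min(polygon[, 1]))); c1 <- min(w - 1L, ceiling(max(polygon[, 1])))
  mask <- matrix(0L, h, w)
  if (r1 < r0 || c1 < c0) stop("polygon rasterized to an empty ROI", call. = FALSE)
  cc <- rep(c0:c1, each = r1 - r0 + 1)   # pixel-center x
  rr <- rep(r0:r1, times = c1 - c0 + 1)  # pixel-center y
  inside <- rep(FALSE, length(cc))
  n <- nrow(polygon)
  j <- n
  for (i in seq_len(n)) {  # even-odd ray casting, vectorized over pixel centers
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    crosses <- ((yi > rr) != (yj > rr)) &
      (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (!any(inside)) stop("polygon rasterized to an empty ROI", call. = FALSE)
  mask[cbind(rr[inside] + 1L, cc[inside] + 1L)] <- 1L
  mask
}

#' Read a grayscale image
#'
#' Reads a PNG image as a single-channel matrix of 8-bit gray intensities in
#' `[0, 255]`. RGB(A) input is collapsed by luminance (0.299 R + 0.587 G +
#' 0.114 B), matching common radiograph JPG/PNG exports.
#'
#' @param path path to a PNG file.
#' @return Numeric matrix (rows = image rows from the top).
#' @export
read_gray_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img * 255
}

#' Write a grayscale image
#'
#' @param pixels numeric matrix with intensities in `[0, 255]`.
#' @param path output PNG path.
#' @export
write_gray_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}

# Clinical table schema. Column names mirror the cohort-description table in
# snake_case; the schema is owned by this package.
CLINICAL_COLUMNS <- c("subject_id", "age_menarche", "height_menarche",
                      "father_height", "mother_height",
                      "ba_gp_reader1", "ba_gp_reader2",
                      "ba_ph_reader1", "ba_ph_reader2", "final_height")

#' Read a clinical table
#'
#' Reads the per-subject clinical CSV (decimal point, UTF-8). Mean bone-age
#' columns `ba_gp_mean` and `ba_ph_mean` are computed as the arithmetic mean of
#' the two readers. Rows violating the plausibility invariants (heights in
#' 100-220 cm, bone ages in 5-20 y) are reported with their row numbers in the
#' `violations` attribute; `final_height` may be `NA` for prediction-only
#' subjects.
#'
#' @param path path to the CSV.
#' @return data.frame of clinical records with derived mean-BA columns and a
#'   `violations` attribute (character vector, empty when clean).
#' @export
read_clinical_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("clinical table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- setdiff(CLINICAL_COLUMNS, "subject_id")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop(sprintf("clinical table parse error: non-numeric value in column '%s', row %d",
                     cl, bad[1]), call. = FALSE)
      df[[cl]] <- conv
    }
  }
  df$ba_gp_mean <- (df$ba_gp_reader1 + df$ba_gp_reader2) / 2
  df$ba_ph_mean <- (df$ba_ph_reader1 + df$ba_ph_reader2) / 2
  attr(df, "violations") <- clinical_violations(df)
  df
}

clinical_violations <- function(df) {
  out <- character(0)
  chk <- function(col, lo, hi, allow_na = FALSE) {
    v <- df[[col]]
    bad <- which(if (allow_na) !is.na(v) & (v < lo | v > hi) else
      is.na(v) | v < lo | v > hi)
    if (length(bad))
      out <<- c(out, sprintf("row %d: %s = %s outside [%g, %g]",
                             bad, col, format(v[bad]), lo, hi))
  }
  for (cl in c("height_menarche", "father_height", "mother_height"))
    chk(cl, 100, 220)
  chk("final_height", 100, 220, allow_na = TRUE)
  for (cl in c("ba_gp_reader1", "ba_gp_reader2", "ba_ph_reader1", "ba_ph_reader2"))
    chk(cl, 5, 20)
  out
}

#' Write a clinical table
#'
#' Inverse of [read_clinical_csv()]; derived mean-BA columns are not written
#' (they are recomputed on read).
#'
#' @param df clinical data.frame.
#' @param path output CSV path.
#' @export
write_clinical_csv <- function(df, path) {
  write.csv(df[, CLINICAL_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a percentage-of-mature-height table
#'
#' Reads a two-column CSV (`bone_age`, `pct_mature`) giving, for each bone
#' age, the average percentage of final height already attained. Bone age
#' must be strictly increasing and the percentage non-decreasing with a final
#' value of at most 100.
#'
#' The package ships `synthetic_bp_girls.csv` under `extdata`: a *synthetic*
#' stand-in table for average-maturing girls, constructed (not transcribed
#' from the published projection tables) and calibrated so hand-wrist
#' projections reproduce the modest systematic overprediction reported for
#' this population. See [bp_predict()].
#'
#' @param path path to the CSV.
#' @return data.frame of class `bp_table` with columns `bone_age`, `pct_mature`.
#' @export
read_bp_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bone_age", "pct_mature") %in% names(df)))
    stop("BP table must have columns bone_age, pct_mature", call. = FALSE)
  validate_bp_table(df)
}

#' @rdname read_bp_table
#' @param df data.frame with columns `bone_age` and `pct_mature`.
#' @export
validate_bp_table <- function(df) {
  if (any(diff(df$bone_age) <= 0))
    stop("BP table bone_age must be strictly increasing", call. = FALSE)
  if (any(diff(df$pct_mature) < 0))
    stop("BP table monotonicity error: pct_mature decreases", call. = FALSE)
  if (any(df$pct_mature <= 0) || df$pct_mature[nrow(df)] > 100)
    stop("BP table pct_mature must lie in (0, 100]", call. = FALSE)
  class(df) <- c("bp_table", "data.frame")
  df
}

#' Default percentage-of-mature-height table
#'
#' Loads the synthetic girls' table shipped with the package (see
#' [read_bp_table()] for its provenance and calibration).
#'
#' @return A `bp_table` data.frame.
#' @export
default_bp_table <- function() {
  read_bp_table(system.file("extdata", "synthetic_bp_girls.csv",
                            package = "radheight", mustWork = TRUE))
}
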