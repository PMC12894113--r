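#' Feature-extraction configuration
#'
#' @param bin_width discretization bin width in intensity units (default 25).
#' @param filters image filters to apply; texture and first-order families
#'   run under each, shape runs under `original` only.
#' @param wavelet wavelet kernel for the filtered bands.
#' @return List of class `extraction_config` with a content hash.
#' @export
extraction_config <- function(bin_width = 25,
                              filters = c("original", "wavelet_L", "wavelet_H"),
                              wavelet = "coif1") {
  filters <- match.arg(filters, c("original", "wavelet_L", "wavelet_H"),
                       several.ok = TRUE)
  cfg <- list(bin_width = bin_width, filters = filters, wavelet = wavelet)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "extraction_config"
  cfg
}

# content hash of any R object via its canonical JSON serialization
config_hash <- function(obj) {
  obj$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

#' Extract every configured radiomic feature from an ROI
#'
#' Applies first-order and all texture families (GLCM, GLRLM, GLSZM, GLDM,
#' NGTDM) under each configured filter, and 2D shape features under the
#' original image only. Feature keys are `filter/feature_class/name`; the key
#' set is a pure function of the configuration, so vectors from different
#' subjects align exactly.
#'
#' @param roi an [roi_image()].
#' @param config an [extraction_config()].
#' @return Named numeric vector (the feature vector), with attributes
#'   `subject_id`, `site`, `config_hash`.
#' @export
extract_all <- function(roi, config = extraction_config()) {
  out <- numeric(0)
  shp <- shape2d_features(roi$mask)
  out <- c(out, setNames(shp, paste0("original/shape2d/", names(shp))))
  for (f in config$filters) {
    px <- switch(f,
      original = roi$pixels,
      wavelet_L = wavelet_filter(roi$pixels, "L", config$wavelet),
      wavelet_H = wavelet_filter(roi$pixels, "H", config$wavelet))
    froi <- roi
    froi$pixels <- px
    fo <- firstorder_features(froi)
    d <- discretize(froi, config$bin_width)
    fam <- list(firstorder = fo,
                glcm = glcm_features(d),
                glrlm = glrlm_features(d),
                glszm = glszm_features(d),
                gldm = gldm_features(d),
                ngtdm = ngtdm_features(d))
    for (cl in names(fam))
      out <- c(out, setNames(fam[[cl]], paste0(f, "/", cl, "/",
                                               names(fam[[cl]]))))
  }
  if (!all(is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  attr(out, "subject_id") <- roi$subject_id
  attr(out, "site") <- roi$site
  attr(out, "config_hash") <- config$hash
  out
}

#' Assemble feature vectors into a matrix
#'
#' @param vectors list of feature vectors from [extract_all()] (one per
#'   subject, identical key sets).
#' @param subject_ids optional subject ids (defaults to the vectors'
#'   `subject_id` attributes).
#' @return Numeric matrix, subjects x features.
#' @export
feature_matrix <- function(vectors, subject_ids = NULL) {
  if (is.null(subject_ids))
    subject_ids <- vapply(vectors, function(v)
      as.character(attr(v, "subject_id")), character(1))
  keys <- names(vectors[[1]])
  for (v in vectors)
    if (!identical(names(v), keys))
      stop("feature vectors have differing key sets", call. = FALSE)
  m <- do.call(rbind, lapply(vectors, as.numeric))
  dimnames(m) <- list(subject_ids, keys)
  m
}

#' Write a feature matrix as tidy and wide CSV
#'
#' The tidy form has one row per (subject, feature) with the key split into
#' `filter`, `feature_class`, `feature_name`; the wide form has one row per
#' subject. The extraction configuration is serialized alongside as JSON with
#' its content hash.
#'
#' @param m feature matrix from [feature_matrix()].
#' @param site anatomical site the matrix belongs to.
#' @param dir output directory.
#' @param config the [extraction_config()] used.
#' @return Invisibly, the paths written.
#' @export
write_feature_matrix <- function(m, site, dir, config = extraction_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- do.call(rbind, strsplit(colnames(m), "/", fixed = TRUE))
  tidy <- data.frame(subject_id = rep(rownames(m), times = ncol(m)),
                     site = site,
                     filter = rep(keys[, 1], each = nrow(m)),
                     feature_class = rep(keys[, 2], each = nrow(m)),
                     feature_name = rep(keys[, 3], each = nrow(m)),
                     value = as.vector(m), stringsAsFactors = FALSE)
  p1 <- file.path(dir, paste0("features_", site, "_tidy.csv"))
  p2 <- file.path(dir, paste0("features_", site, "_wide.csv"))
  p3 <- file.path(dir, paste0("features_", site, "_config.json"))
  write.csv(tidy, p1, row.names = FALSE, quote = FALSE)
  wide <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  write.csv(wide, p2, row.names = FALSE)
  jsonlite::write_json(unclass(config), p3, auto_unbox = TRUE, digits = NA)
  invisible(c(tidy = p1, wide = p2, config = p3))
}
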