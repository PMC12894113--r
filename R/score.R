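#' Radiomic score definition
#'
#' A score definition is the linear form `S = intercept + sum(coef_j * z_j)`
#' over (optionally standardized) feature values, together with the
#' standardization block needed to compute each `z_j`. The reported radiomic
#' score is the signed log transform `Sign(S) * log(|S|)` (natural log); see
#' [radiomic_score()].
#'
#' @param site anatomical site (`"distal_femur"` or `"proximal_tibia"`).
#' @param intercept numeric intercept of the linear form.
#' @param coefficients named numeric vector of feature coefficients; names
#'   are feature keys `filter/feature_class/name` (e.g.
#'   `"wavelet_L/glrlm/RunLengthNonUniformity"`) or any columns present in
#'   the feature matrix the score will be applied to.
#' @param standardization data.frame with columns `feature`, `mean`, `sd`
#'   giving the per-feature training standardization, or `NULL` for identity
#'   standardization (coefficients applied to raw feature values).
#' @param lambda optional penalty at which the definition was selected.
#' @return Object of class `score_definition`.
#' @export
score_definition <- function(site, intercept, coefficients,
                             standardization = NULL, lambda = NA_real_) {
  site <- match.arg(site, ROI_SITES)
  if (!is.null(standardization)) {
    stopifnot(all(c("feature", "mean", "sd") %in% names(standardization)))
    if (any(standardization$sd <= 0))
      stop("standardization sd must be positive", call. = FALSE)
    if (!setequal(standardization$feature, names(coefficients)))
      stop("standardization block must cover exactly the score terms",
           call. = FALSE)
  }
  structure(list(site = site, intercept = unname(intercept),
                 coefficients = coefficients,
                 standardization = standardization, lambda = lambda),
            class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s: intercept %.4f + %d term(s), %s standardization\n",
              x$site, x$intercept, length(x$coefficients),
              if (is.null(x$standardization)) "identity" else "stored"))
  invisible(x)
}

#' Evaluate a radiomic score
#'
#' Computes `S = intercept + sum(coef_j * z_j)` with `z_j` the (standardized)
#' feature values, and the score `Sign(S) * log(|S|)` (natural logarithm).
#' The transform is odd in `S` and zero at `|S| = 1`; it diverges as `S`
#' approaches 0, so inputs with `|S| <= eps` raise a near-singularity error
#' rather than being clamped.
#'
#' @param def a [score_definition()].
#' @param features named numeric vector (or single-row data.frame) of feature
#'   values containing every term of the definition.
#' @param eps guard on `|S|` (default 1e-8).
#' @return List with `S` and `score`.
#' @export
radiomic_score <- function(def, features, eps = 1e-8) {
  if (is.data.frame(features)) features <- unlist(features[1, , drop = TRUE])
  need <- names(def$coefficients)
  missing_f <- setdiff(need, names(features))
  if (length(missing_f))
    stop("missing feature(s) for score: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  z <- as.numeric(features[need])
  if (!is.null(def$standardization)) {
    stdz <- def$standardization[match(need, def$standardization$feature), ]
    z <- (z - stdz$mean) / stdz$sd
  }
  S <- def$intercept + sum(def$coefficients * z)
  if (!is.finite(S) || abs(S) <= eps)
    stop("near-singular score: |S| <= ", eps, call. = FALSE)
  list(S = S, score = sign(S) * log(abs(S)))
}

#' Read and write score-definition coefficient tables
#'
#' Score definitions are exchanged as CSV with columns `anatomical_site`,
#' `filter`, `feature_class`, `feature_name`, `coefficient` (the intercept is
#' the row with filter/class/name all `"Intercept"`). Feature keys are formed
#' as `filter/feature_class/feature_name`.
#'
#' The package ships `score_coefficients.csv` under `extdata`: a published
#' reference signature for knee epiphyses of girls at menarche, with the
#' coefficients exactly as printed. Both sites carry the same printed
#' intercept (160.0959), possibly a typographical artifact of the source
#' table; it is shipped as printed. The source publishes no standardization
#' block, so definitions read from CSV default to identity standardization
#' unless one is attached explicitly.
#'
#' @param path CSV path.
#' @param site which site's definition to extract.
#' @return `read_score_csv()`: a [score_definition()] (identity
#'   standardization).
#' @export
read_score_csv <- function(path, site = c("distal_femur", "proximal_tibia")) {
  site <- match.arg(site)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("anatomical_site", "filter", "feature_class", "feature_name",
            "coefficient")
  if (!all(need %in% names(df)))
    stop("score CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[df$anatomical_site == site, ]
  if (nrow(df) == 0) stop("no rows for site ", site, call. = FALSE)
  is_int <- df$feature_class == "Intercept" | df$feature_name == "Intercept"
  if (sum(is_int) != 1) stop("score CSV needs exactly one intercept row per site",
                             call. = FALSE)
  terms <- df[!is_int, ]
  cf <- setNames(terms$coefficient,
                 paste(terms$filter, terms$feature_class, terms$feature_name,
                       sep = "/"))
  score_definition(site = site, intercept = df$coefficient[is_int],
                   coefficients = cf, standardization = NULL)
}

#' @rdname read_score_csv
#' @param def a [score_definition()] whose terms use `filter/class/name` keys.
#' @export
write_score_csv <- function(def, path) {
  df <- data.frame(anatomical_site = def$site, filter = "Intercept",
                   feature_class = "Intercept", feature_name = "Intercept",
                   coefficient = def$intercept, stringsAsFactors = FALSE)
  if (length(def$coefficients)) {
    keys <- do.call(rbind, strsplit(names(def$coefficients), "/",
                                    fixed = TRUE))
    df <- rbind(df, data.frame(
      anatomical_site = def$site, filter = keys[, 1],
      feature_class = keys[, 2], feature_name = keys[, 3],
      coefficient = unname(def$coefficients), stringsAsFactors = FALSE))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference score definition shipped with the package
#'
#' Loads the published reference signature (see [read_score_csv()]) for a
#' site. Identity standardization: the printed coefficients are applied to
#' feature values as-is.
#'
#' @param site `"distal_femur"` or `"proximal_tibia"`.
#' @return A [score_definition()].
#' @export
reference_score_definition <- function(site = c("distal_femur",
                                                "proximal_tibia")) {
  site <- match.arg(site)
  read_score_csv(system.file("extdata", "score_coefficients.csv",
                             package = "radheight", mustWork = TRUE), site)
}
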