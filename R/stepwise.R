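#' Forward stepwise OLS selection
#'
#' Builds a prediction equation starting from the constant model. At each
#' iteration the candidate most strongly associated with the current
#' residuals (largest absolute correlation, equivalent to the largest
#' F-to-enter) is trialed; it is accepted iff the nested F-test of the
#' extended model against the current one has `P < entry_alpha` and the
#' entering variable's own t-test has `P < retain_alpha`. For a single added
#' variable these two P values coincide, so the entry threshold is the
#' binding one. A rejected candidate is excluded from further candidacy and
#' the search continues with the remaining ones; selection is forward-only
#' (entered variables are never removed) and terminates when no candidate
#' remains.
#'
#' Degenerate candidates (zero variance or collinear with the current model)
#' are recorded in the trace as rejected with a collinearity note and never
#' enter.
#'
#' @param candidates data.frame of candidate predictors (named columns).
#' @param y outcome vector (final height, cm).
#' @param entry_alpha threshold on the model-improvement F-test P (default
#'   0.05).
#' @param retain_alpha threshold on the entering variable's P (default 0.10).
#' @return List with `fit` (the final [ols_fit()]; the constant model if
#'   nothing entered) and `trace` (data.frame: step, candidate, model_f_p,
#'   variable_p, accepted, note).
#' @export
stepwise_select <- function(candidates, y, entry_alpha = 0.05,
                            retain_alpha = 0.10) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  remaining <- names(candidates)
  selected <- character(0)
  current <- ols_fit(candidates[, selected, drop = FALSE], y)
  trace <- data.frame(step = integer(0), candidate = character(0),
                      model_f_p = numeric(0), variable_p = numeric(0),
                      accepted = logical(0), note = character(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    resid <- stats::residuals(current$lm)
    assoc <- vapply(remaining, function(v) {
      x <- candidates[[v]]
      if (var(x) == 0) return(NA_real_)
      suppressWarnings(abs(cor(resid, x)))
    }, numeric(1))
    if (all(is.na(assoc))) {
      trace <- rbind(trace, data.frame(
        step = step, candidate = remaining[1], model_f_p = NA, variable_p = NA,
        accepted = FALSE, note = "collinear or constant",
        stringsAsFactors = FALSE))
      break
    }
    best <- remaining[which.max(assoc)]
    trial <- tryCatch(
      ols_fit(candidates[, c(selected, best), drop = FALSE], y),
      error = function(e) e)
    if (inherits(trial, "error")) {
      trace <- rbind(trace, data.frame(
        step = step, candidate = best, model_f_p = NA, variable_p = NA,
        accepted = FALSE, note = "collinear with current model",
        stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, best)
      next
    }
    ft <- nested_f_test(current, trial)
    var_p <- trial$coefficients$p[match(best, trial$coefficients$term)]
    accepted <- ft$p < entry_alpha && var_p < retain_alpha
    trace <- rbind(trace, data.frame(
      step = step, candidate = best, model_f_p = ft$p, variable_p = var_p,
      accepted = accepted, note = "", stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, best)
    if (accepted) {
      selected <- c(selected, best)
      current <- trial
    }
  }
  list(fit = current, trace = trace)
}

#' Clinical + imaging candidate set for the final-height equation
#'
#' Convenience constructor of the standard candidate data.frame used in the
#' stepwise selection: father's and mother's height, height at menarche, the
#' two mean bone-age readings, and the femur and tibia radiomic scores.
#'
#' @param clinical clinical data.frame (see [read_clinical_csv()]).
#' @param femur_score,tibia_score per-subject radiomic scores, aligned with
#'   `clinical` rows.
#' @return data.frame of the seven candidate predictors.
#' @export
height_candidates <- function(clinical, femur_score, tibia_score) {
  data.frame(
    father_height = clinical$father_height,
    mother_height = clinical$mother_height,
    height_menarche = clinical$height_menarche,
    ba_gp_mean = clinical$ba_gp_mean,
    ba_ph_mean = clinical$ba_ph_mean,
    femur_score = femur_score,
    tibia_score = tibia_score)
}
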