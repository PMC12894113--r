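#' Pipeline run configuration
#'
#' Bundles the input layout (a cohort directory as written by
#' [generate_cohort()], or equivalently images/, annotations/, clinical.csv
#' collected from an annotation tool), the analysis thresholds, and the run
#' seed. Thresholds default to the standard operating point: ICC gate 0.8,
#' variance threshold 0.8, univariate alpha 0.05, stepwise entry alpha 0.05
#' and retention alpha 0.10, five CV folds.
#'
#' @param cohort_dir directory containing `clinical.csv` and (unless
#'   `use_images = FALSE`) `images/` and `annotations/`.
#' @param out_dir run output directory.
#' @param seed master seed; every stage derives its substream from it by a
#'   stage-name-keyed scheme, so toggling one stage does not perturb
#'   another's draws.
#' @param icc_threshold,variance_threshold,univariate_alpha analysis
#'   thresholds for the reliability gate, variance filter and univariate
#'   screen.
#' @param entry_alpha,retain_alpha,k stepwise entry/retention thresholds and
#'   the CV fold count.
#' @param bin_width discretization bin width for feature extraction.
#' @param bp_table_path optional CSV path for the percentage-of-mature-height
#'   table; default uses the shipped synthetic table.
#' @param use_images run the imaging stages (set `FALSE` for clinical-only
#'   cohorts with precomputed scores).
#' @return List of class `run_config`.
#' @export
run_config <- function(cohort_dir, out_dir, seed = 1,
                       icc_threshold = 0.8, variance_threshold = 0.8,
                       univariate_alpha = 0.05, entry_alpha = 0.05,
                       retain_alpha = 0.10, k = 5, bin_width = 25,
                       bp_table_path = NULL, use_images = TRUE) {
  thr <- c(icc_threshold = icc_threshold,
           variance_threshold = variance_threshold,
           univariate_alpha = univariate_alpha, entry_alpha = entry_alpha,
           retain_alpha = retain_alpha)
  bad <- thr[!(thr > 0 & (thr <= 1 | names(thr) == "variance_threshold"))]
  if (length(bad))
    stop("threshold(s) out of range: ", paste(names(bad), collapse = ", "),
         call. = FALSE)
  structure(list(cohort_dir = cohort_dir, out_dir = out_dir, seed = seed,
                 icc_threshold = icc_threshold,
                 variance_threshold = variance_threshold,
                 univariate_alpha = univariate_alpha,
                 entry_alpha = entry_alpha, retain_alpha = retain_alpha,
                 k = k, bin_width = bin_width,
                 bp_table_path = bp_table_path, use_images = use_images),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Checks the cohort directory for schema conformance and subject alignment
#' (every subject needs an image and an observer-1 annotation per site) and
#' the configuration thresholds for range. Issues are reported, never
#' thrown; subjects lacking a final height are flagged as prediction-only.
#'
#' @param config a [run_config()].
#' @return data.frame with columns `level` (`"error"`/`"warning"`/`"info"`)
#'   and `message`; zero rows when fully valid.
#' @export
validate_inputs <- function(config) {
  issues <- data.frame(level = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(level, msg) issues <<- rbind(
    issues, data.frame(level = level, message = msg, stringsAsFactors = FALSE))
  clin_path <- file.path(config$cohort_dir, "clinical.csv")
  if (!file.exists(clin_path)) {
    add("error", paste("missing clinical table:", clin_path))
    return(issues)
  }
  clin <- tryCatch(read_clinical_csv(clin_path), error = function(e) e)
  if (inherits(clin, "error")) {
    add("error", conditionMessage(clin))
    return(issues)
  }
  for (v in attr(clin, "violations")) add("warning", v)
  pred_only <- clin$subject_id[is.na(clin$final_height)]
  for (s in pred_only) add("info", paste("prediction-only subject:", s))
  if (config$k > nrow(clin) - length(pred_only))
    add("error", sprintf("k = %d folds exceed the %d subjects with outcomes",
                         config$k, nrow(clin) - length(pred_only)))
  if (config$use_images) {
    for (sid in clin$subject_id) {
      for (site in ROI_SITES) {
        img <- file.path(config$cohort_dir, "images",
                         paste0(sid, "_", site, ".png"))
        ann <- file.path(config$cohort_dir, "annotations",
                         paste0(sid, "_", site, "_obs1.json"))
        if (!file.exists(img)) add("error", paste("missing image:", img))
        if (!file.exists(ann)) add("error", paste("missing annotation:", ann))
      }
    }
  }
  issues
}

# read one subject-site ROI from a cohort directory
.load_roi <- function(dir, sid, site, tag = "obs1") {
  img <- read_gray_image(file.path(dir, "images",
                                   paste0(sid, "_", site, ".png")))
  ann <- read_labelme_annotation(
    file.path(dir, "annotations", paste0(sid, "_", site, "_", tag, ".json")))
  mask <- rasterize_polygon(ann[[site]], dim(img))
  roi_image(img, mask, site = site, subject_id = sid, observer_id = tag)
}

.extract_set <- function(dir, sids, site, tag, ecfg) {
  feature_matrix(lapply(sids, function(sid)
    extract_all(.load_roi(dir, sid, site, tag), ecfg)), subject_ids = sids)
}

#' Run the full analysis pipeline
#'
#' Executes extract -> reliability gate -> variance filter -> univariate
#' screen -> LASSO -> radiomic scores -> stepwise OLS -> five-fold CV ->
#' method comparison, writing every intermediate table, the fit report, the
#' evaluation table and a machine-readable manifest (configuration hash,
#' seed, package version, stage log with wall times, output checksums) into
#' the output directory. A stage failure halts the run with the failing
#' stage named; outputs of completed stages are preserved on disk.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the principal in-memory results
#'   (`reliability`, `selection`, `score_definitions`, `scores`, `stepwise`,
#'   `comparison`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage_log <- function(stage, t0) {
    line <- sprintf("[%s] %s: %.2f s", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(Sys.time()) - t0)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    stage_log(stage, t0)
    out
  }
  issues <- run_stage("validate", validate_inputs(config))
  if (any(issues$level == "error"))
    stop("stage 'validate' failed:\n",
         paste(issues$message[issues$level == "error"], collapse = "\n"),
         call. = FALSE)
  clin <- read_clinical_csv(file.path(config$cohort_dir, "clinical.csv"))
  fitted_ids <- clin$subject_id[!is.na(clin$final_height)]
  ecfg <- extraction_config(bin_width = config$bin_width)
  bp_tab <- if (is.null(config$bp_table_path)) default_bp_table() else
    read_bp_table(config$bp_table_path)

  score_defs <- list(); scores <- list(); reliability <- list()
  selection <- list()
  if (config$use_images) {
    ann_dir <- file.path(config$cohort_dir, "annotations")
    for (site in ROI_SITES) {
      feats <- run_stage(paste0("extract_", site),
                         .extract_set(config$cohort_dir, clin$subject_id,
                                      site, "obs1", ecfg))
      has_tag <- function(tag) clin$subject_id[file.exists(file.path(
        ann_dir, paste0(clin$subject_id, "_", site, "_", tag, ".json")))]
      inter_ids <- has_tag("obs2"); intra_ids <- has_tag("obs1_repeat")
      rel <- run_stage(paste0("stability_", site), {
        inter_b <- .extract_set(config$cohort_dir, inter_ids, site, "obs2",
                                ecfg)
        intra_b <- .extract_set(config$cohort_dir, intra_ids, site,
                                "obs1_repeat", ecfg)
        stability_filter(feats[inter_ids, , drop = FALSE], inter_b,
                         feats[intra_ids, , drop = FALSE], intra_b,
                         threshold = config$icc_threshold)
      })
      reliability[[site]] <- rel
      stable <- rel$feature[rel$pass]
      fm <- feats[fitted_ids, stable, drop = FALSE]
      y <- clin$final_height[match(fitted_ids, clin$subject_id)]
      sel <- run_stage(paste0("select_", site), {
        kept_var <- variance_filter(fm, threshold = config$variance_threshold)
        uni <- univariate_screen(fm[, kept_var, drop = FALSE], y,
                                 alpha = config$univariate_alpha)
        kept_uni <- uni$feature[uni$keep]
        list(stable = stable, kept_var = kept_var, univariate = uni,
             kept_uni = kept_uni)
      })
      selection[[site]] <- sel
      def <- run_stage(paste0("lasso_", site), {
        if (length(sel$kept_uni) >= 2)
          lasso_select(fm[, sel$kept_uni, drop = FALSE], y, site = site,
                       seed = derive_seed(config$seed, paste0("lasso_", site)))
        else score_definition(site, intercept = mean(y),
                              coefficients = setNames(numeric(0),
                                                      character(0)))
      })
      score_defs[[site]] <- def
      scores[[site]] <- vapply(clin$subject_id, function(sid)
        radiomic_score(def, feats[sid, ])$score, numeric(1))
    }
  } else {
    # clinical-only runs expect precomputed score columns in ground truth
    gt <- jsonlite::read_json(file.path(config$cohort_dir,
                                        "ground_truth.json"),
                              simplifyVector = TRUE)
    scores$distal_femur <- setNames(gt$truth$femur_score, gt$truth$subject_id)
    scores$proximal_tibia <- setNames(gt$truth$tibia_score,
                                      gt$truth$subject_id)
  }

  fitted <- clin[match(fitted_ids, clin$subject_id), ]
  fitted$femur_score <- scores$distal_femur[fitted_ids]
  fitted$tibia_score <- scores$proximal_tibia[fitted_ids]
  sw <- run_stage("stepwise", {
    cand <- height_candidates(fitted, fitted$femur_score, fitted$tibia_score)
    keep <- vapply(cand, function(x) var(x) > 1e-12, logical(1))
    stepwise_select(cand[, keep, drop = FALSE], fitted$final_height,
                    entry_alpha = config$entry_alpha,
                    retain_alpha = config$retain_alpha)
  })
  cmp <- run_stage("evaluate", {
    methods <- c("ols_eq2", "gp_bp", "ph_bp", "target_height")
    if (var(fitted$femur_score) > 1e-12)
      methods <- c("ols_eq1", methods, "ols_eq3")
    compare_methods(fitted, methods = methods,
                    plan = cv_plan(nrow(fitted), k = config$k,
                                   seed = derive_seed(config$seed, "cv")),
                    bp_table = bp_tab)
  })

  out <- config$out_dir
  run_stage("write_outputs", {
    if (length(reliability))
      for (site in names(reliability))
        write.csv(reliability[[site]],
                  file.path(out, paste0("reliability_", site, ".csv")),
                  row.names = FALSE)
    if (length(selection))
      jsonlite::write_json(selection, file.path(out, "selection.json"),
                           auto_unbox = TRUE, digits = NA)
    for (site in names(score_defs))
      write_score_csv(score_defs[[site]],
                      file.path(out, paste0("score_definition_", site,
                                            ".csv")))
    write.csv(data.frame(subject_id = fitted_ids,
                         femur_score = unname(fitted$femur_score),
                         tibia_score = unname(fitted$tibia_score)),
              file.path(out, "radiomic_scores.csv"), row.names = FALSE)
    writeLines(format_equation_fit(sw$fit), file.path(out, "fit_report.txt"))
    jsonlite::write_json(
      list(predictors = sw$fit$predictors,
           coefficients = sw$fit$coefficients, r2 = sw$fit$r2,
           adj_r2 = sw$fit$adj_r2, f_stat = sw$fit$f_stat, f_p = sw$fit$f_p,
           aic = sw$fit$aic, bic = sw$fit$bic, n = sw$fit$n,
           trace = sw$trace),
      file.path(out, "fit_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    write.csv(cmp$table, file.path(out, "evaluation.csv"), row.names = FALSE)
    TRUE
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("radheight")),
    seed = config$seed,
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    stages = log_lines,
    outputs = as.list(tools::md5sum(list.files(out, full.names = TRUE,
                                               pattern = "\\.(csv|txt|json)$"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(reliability = reliability, selection = selection,
                 score_definitions = score_defs, scores = scores,
                 stepwise = sw, comparison = cmp, manifest = manifest))
}
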