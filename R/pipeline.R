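#' Run the full pain-estimation pipeline on a cohort
#'
#' Convenience driver covering the whole analysis: build the matched feature
#' table (segment, match, extract), drop rows with missing feature entries,
#' run wrapper feature selection with the chosen regression family, score
#' the selected set out-of-fold (RMSE, Pearson r, residuals), and compare
#' the regressor-as-classifier against a native four-level SVM on the same
#' feature set and folds.
#'
#' @param cohort List of [session_bundle()] (or a single bundle), e.g. from
#'   [generate_cohort()] or read from CSVs.
#' @param spec Regression [model_spec()] (default SVR).
#' @param direction Wrapper search direction, `"forward"` or `"backward"`.
#' @param k Cross-validation folds (default 10).
#' @param seed Seed controlling fold assignment.
#' @param tol Wrapper stopping tolerance.
#' @param max_features Cap on forward-selected features (`Inf` = none).
#' @param select If `FALSE`, skip selection and use all complete features.
#' @param mcfg,fcfg Matching and filter configurations.
#' @return List of class `pain_pipeline_result` with elements `table` (the
#'   feature table), `selection`, `regression` (list: `rmse`, `pearson_r`,
#'   `baseline_sd`, `predictions`, `residuals`), `classification` (list:
#'   `svm`, `svr_as_classifier` reports) and `n` (samples used).
#' @export
run_pain_pipeline <- function(cohort, spec = model_spec("svr"),
                              direction = "forward", k = 10L, seed = 1L,
                              tol = 1e-4, max_features = Inf,
                              select = TRUE,
                              mcfg = match_config(), fcfg = filter_config()) {
  tbl <- build_feature_table(cohort, mcfg, fcfg)
  feats <- intersect(pain_feature_names(), names(tbl))
  # keep features observed everywhere; drop zero-variance columns, which
  # carry no information and only pad the wrapper's candidate set
  feats <- feats[colSums(is.na(tbl[feats])) == 0]
  feats <- feats[apply(tbl[feats], 2, stats::var) > 0]
  stopifnot(length(feats) >= 1L, nrow(tbl) >= k)
  X <- tbl[, feats, drop = FALSE]
  y <- tbl$score

  sel <- NULL
  use <- feats
  if (isTRUE(select)) {
    sel <- wrapper_select(X, y, spec, direction = direction, k = k,
                          seed = seed, tol = tol,
                          max_features = max_features)
    if (length(sel$selected)) use <- sel$selected
  }

  folds <- cv_folds(nrow(X), k, seed)
  pred <- as.numeric(cv_predict(spec, X[, use, drop = FALSE], y,
                                folds = folds))
  reg <- list(rmse = rmse(y, pred),
              pearson_r = pearson_r(y, pred),
              baseline_sd = pop_sd(y),
              predictions = pred,
              residuals = residual_table(y, pred))

  y_cat <- categorize(y)
  svm_spec <- model_spec("svm", cost = spec$cost, gamma = spec$gamma)
  svm_pred <- cv_predict(svm_spec, X[, use, drop = FALSE], y_cat,
                         k = k, seed = seed)
  cls <- list(svm = classification_report(y_cat, svm_pred),
              svr_as_classifier = regression_as_classifier(y, pred))

  structure(list(table = tbl, selection = sel, regression = reg,
                 classification = cls, n = nrow(tbl)),
            class = "pain_pipeline_result")
}

#' @export
print.pain_pipeline_result <- function(x, ...) {
  cat(sprintf("pain pipeline: %d matched samples\n", x$n))
  if (!is.null(x$selection))
    cat(sprintf("  selected (%s): %s\n", x$selection$direction,
                paste(x$selection$selected, collapse = ", ")))
  cat(sprintf("  regression : RMSE %.3f (baseline sd %.3f), r %.3f\n",
              x$regression$rmse, x$regression$baseline_sd,
              x$regression$pearson_r))
  cat(sprintf("  classes    : SVM acc %.3f wF1 %.3f | regressor acc %.3f wF1 %.3f\n",
              x$classification$svm$accuracy,
              x$classification$svm$weighted_f1,
              x$classification$svr_as_classifier$accuracy,
              x$classification$svr_as_classifier$weighted_f1))
  invisible(x)
}
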