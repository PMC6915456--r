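#' Root mean square error
#'
#' `sqrt(mean((actual - predicted)^2))`, in pain-score units. Predicting the
#' mean of the actual values gives the population standard deviation of the
#' target — the "mean-only" baseline any useful model must beat.
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(0, 4), c(2, 2))  # 2
rmse <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) > 0)
  sqrt(mean((actual - predicted)^2))
}

#' Population standard deviation
#'
#' The `1/n` form, i.e. the RMSE of the mean-only baseline.
#'
#' @param x Numeric vector.
#' @return Non-negative scalar.
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Pearson correlation between actual and predicted values
#'
#' @param actual,predicted Equal-length numeric vectors of length >= 2 with
#'   nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("pearson_r undefined: zero-variance input")
  stats::cor(actual, predicted)
}

#' Pain category levels
#' @return The ordered levels `none < mild < moderate < severe`.
#' @export
pain_levels <- function() c("none", "mild", "moderate", "severe")

#' Categorize a 0-10 pain score on the four-level scale
#'
#' Integer anchors: none (0), mild (1-3), moderate (4-6), severe (7-10).
#' Fractional scores use the half-open extension none < 1 <= mild < 4 <=
#' moderate < 7 <= severe, so an app-logged 0.41 is "none" and 3.999 is
#' still "mild".
#'
#' @param score Numeric vector in \[0, 10\].
#' @return Ordered factor with levels [pain_levels()].
#' @export
#' @examples
#' categorize(c(0, 0.41, 3, 5, 7, 10))
categorize <- function(score) {
  stopifnot(all(score >= 0 & score <= 10))
  lab <- ifelse(score < 1, "none",
         ifelse(score < 4, "mild",
         ifelse(score < 7, "moderate", "severe")))
  factor(lab, levels = pain_levels(), ordered = TRUE)
}

#' Support-weighted mean of per-class F1 scores
#'
#' `sum(support * f1) / sum(support)` over classes with positive support;
#' zero-support classes contribute to neither numerator nor denominator.
#'
#' @param f1 Per-class F1 scores (NA allowed for zero-support classes).
#' @param support Per-class actual counts, aligned with `f1`.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' weighted_f1(c(0, 0, 0.537, 0.786), c(2, 4, 34, 67))
weighted_f1 <- function(f1, support) {
  stopifnot(length(f1) == length(support), all(support >= 0))
  keep <- support > 0
  stopifnot(all(is.finite(f1[keep])))
  sum(f1[keep] * support[keep]) / sum(support[keep])
}

#' Classification report on the four-level pain scale
#'
#' Accuracy, per-class precision/recall/F1 (F1 = 0 when precision + recall
#' = 0) and the support-weighted F1. Classes absent from the actual labels
#' are reported with `NA` F1 and excluded from the weighted average.
#'
#' @param actual,predicted Equal-length factors on [pain_levels()] (plain
#'   vectors are coerced).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `support`
#'   (named by level) and `weighted_f1`.
#' @export
classification_report <- function(actual, predicted) {
  lv <- pain_levels()
  actual <- factor(as.character(actual), levels = lv, ordered = TRUE)
  predicted <- factor(as.character(predicted), levels = lv, ordered = TRUE)
  stopifnot(length(actual) == length(predicted), length(actual) > 0,
            !anyNA(actual), !anyNA(predicted))
  tab <- table(actual = actual, predicted = predicted)
  tp <- diag(tab)
  support <- rowSums(tab)
  pred_n <- colSums(tab)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  f1[support == 0] <- NA_real_
  precision[support == 0 & pred_n == 0] <- NA_real_
  recall[support == 0] <- NA_real_
  list(accuracy = sum(tp) / length(actual),
       precision = precision, recall = recall, f1 = f1,
       support = support,
       weighted_f1 = weighted_f1(f1, support))
}

#' Evaluate continuous predictions on the four-level scale
#'
#' Clamps predicted scores into \[0, 10\], categorizes both vectors and
#' produces a [classification_report()] — the route by which a regression
#' model is compared against a native classifier.
#'
#' @param actual_scores,predicted_scores Numeric pain scores; predictions
#'   may fall outside \[0, 10\] and are clamped first.
#' @return As [classification_report()].
#' @export
regression_as_classifier <- function(actual_scores, predicted_scores) {
  predicted_scores <- pmin(10, pmax(0, predicted_scores))
  classification_report(categorize(actual_scores),
                        categorize(predicted_scores))
}

#' Residual table for diagnostic plots
#'
#' @param actual,predicted Equal-length numeric vectors.
#' @param path Optional CSV output path.
#' @return `data.frame` with columns `actual`, `predicted`, `residual`
#'   (= actual - predicted); the population SD of the actual scores (the
#'   +/- band drawn on residual plots) is attached as attribute `sd_band`.
#' @export
residual_table <- function(actual, predicted, path = NULL) {
  stopifnot(length(actual) == length(predicted), length(actual) > 0)
  out <- data.frame(actual = actual, predicted = predicted,
                    residual = actual - predicted)
  attr(out, "sd_band") <- pop_sd(actual)
  if (!is.null(path)) {
    w <- out
    for (cn in names(w)) w[[cn]] <- fmt_num(w[[cn]])
    utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  }
  out
}
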