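#' Model specification
#'
#' The model families used for between-subject pain estimation: penalised
#' linear regression (`ridge`, `lasso`), Gaussian-process regression
#' (`gpr`), support-vector regression (`svr`), and a support-vector
#' classifier (`svm`) on the four-level pain scale. All kernel methods use
#' the RBF kernel with the kernel scale set on each training fold by the
#' median-distance heuristic, so SVR and SVM are compared with the same
#' kernel.
#'
#' Hyperparameters are fixed per run (no nested tuning): `lambda`
#' regularisation strength for ridge/lasso (default 1.0 on standardized
#' features), `cost` and `epsilon` for SVR (defaults 1.0 and 0.1), `cost`
#' for SVM (default 1.0), observation noise `var` for GPR (default 0.1).
#' `gamma` overrides the median-heuristic RBF scale when given.
#'
#' @param family One of `"ridge"`, `"lasso"`, `"gpr"`, `"svr"`, `"svm"`.
#' @param standardize Center/scale features using training-fold parameters
#'   (default `TRUE`).
#' @param lambda,cost,epsilon,var,gamma Hyperparameters, see above.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("svr", "ridge", "lasso", "gpr", "svm"),
                       standardize = TRUE, lambda = 1.0, cost = 1.0,
                       epsilon = 0.1, var = 0.1, gamma = NULL) {
  family <- match.arg(family)
  structure(list(family = family, standardize = isTRUE(standardize),
                 lambda = lambda, cost = cost, epsilon = epsilon,
                 var = var, gamma = gamma),
            class = "model_spec")
}

is_classifier <- function(spec) spec$family == "svm"

# median pairwise Euclidean distance -> RBF gamma = 1 / (2 * med^2)
median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  if (n > 200L) X <- X[seq(1L, n, length.out = 200L), , drop = FALSE]
  d <- stats::dist(X)
  med <- stats::median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1)
  1 / (2 * med^2)
}

scale_params <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scale <- function(X, sp) sweep(sweep(X, 2, sp$mu), 2, sp$sd, "/")

as_X <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values; drop or ",
                     "impute flagged rows upstream")
  X
}

# fit one model on a training set; returns a closure predicting new rows
fit_one <- function(spec, X, y) {
  X <- as_X(X)
  p <- ncol(X)
  if (p == 0L || (is.numeric(y) && stats::var(y) == 0)) {
    # empty feature set or constant target: intercept-only model
    if (is_classifier(spec)) {
      lev <- levels(y)
      mode_cl <- lev[which.max(tabulate(y, nbins = length(lev)))]
      return(function(Xn) factor(rep(mode_cl, nrow(Xn)),
                                 levels = lev, ordered = is.ordered(y)))
    }
    m <- mean(y)
    return(function(Xn) rep(m, nrow(Xn)))
  }
  sp <- if (spec$standardize) scale_params(X) else
    list(mu = rep(0, p), sd = rep(1, p))
  Xs <- apply_scale(X, sp)
  prep <- function(Xn) apply_scale(as_X(Xn), sp)

  if (spec$family %in% c("ridge", "lasso")) {
    if (p == 1L) Xs <- cbind(Xs, `..aug` = 0)  # glmnet needs >= 2 columns
    fit <- glmnet::glmnet(Xs, y, alpha = if (spec$family == "lasso") 1 else 0,
                          lambda = spec$lambda, standardize = FALSE)
    return(function(Xn) {
      Z <- prep(Xn)
      if (p == 1L) Z <- cbind(Z, `..aug` = 0)
      as.numeric(stats::predict(fit, newx = Z, s = spec$lambda))
    })
  }

  g <- if (is.null(spec$gamma)) median_heuristic_gamma(Xs) else spec$gamma

  if (spec$family == "gpr") {
    fit <- kernlab::gausspr(Xs, y, kernel = "rbfdot",
                            kpar = list(sigma = g), var = spec$var,
                            scaled = FALSE)
    return(function(Xn) as.numeric(kernlab::predict(fit, prep(Xn))))
  }
  if (spec$family == "svr") {
    fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                      gamma = g, cost = spec$cost, epsilon = spec$epsilon,
                      scale = FALSE)
    return(function(Xn) as.numeric(stats::predict(fit, prep(Xn))))
  }
  # svm classifier on the 4-level scale
  stopifnot(is.factor(y))
  if (nlevels(droplevels(y)) < 2L) {
    only <- as.character(droplevels(y)[1])
    return(function(Xn) factor(rep(only, nrow(Xn)), levels = levels(y),
                               ordered = is.ordered(y)))
  }
  fit <- e1071::svm(Xs, factor(y, ordered = FALSE), type = "C-classification",
                    kernel = "radial", gamma = g, cost = spec$cost,
                    scale = FALSE)
  function(Xn) {
    pr <- stats::predict(fit, prep(Xn))
    factor(as.character(pr), levels = levels(y), ordered = is.ordered(y))
  }
}

#' Cross-validation fold assignment
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed; fully determines the assignment.
#' @param strata Optional factor for stratified assignment (classification).
#' @return Integer vector of fold labels in `1:k`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L, strata = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L, k <= n)
  set.seed(as.integer(seed))
  folds <- integer(n)
  if (is.null(strata)) {
    folds <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(strata) == n)
    for (lv in unique(strata)) {
      i <- which(strata == lv)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  }
  folds
}

#' Out-of-fold predictions under k-fold cross-validation
#'
#' Every sample receives exactly one prediction, produced by a model that
#' never saw it; standardization and the RBF median heuristic are fit on the
#' training folds only.
#'
#' @param spec A [model_spec()].
#' @param X Feature `data.frame`/matrix (no missing values).
#' @param y Numeric target (regression) or factor (svm).
#' @param k Folds (default 10; `k = n` gives leave-one-out).
#' @param seed Seed for the fold assignment.
#' @param folds Optional explicit fold labels (overrides `k`/`seed`), e.g.
#'   session labels for leakage-aware grouped CV.
#' @return Vector of out-of-fold predictions aligned with the rows of `X`;
#'   fold labels attached as attribute `folds`.
#' @export
cv_predict <- function(spec, X, y, k = 10L, seed = 1L, folds = NULL) {
  X <- as_X(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2L)
  if (is.null(folds)) {
    folds <- cv_folds(n, k, seed,
                      strata = if (is_classifier(spec)) y else NULL)
  } else {
    folds <- as.integer(factor(folds))
    stopifnot(length(folds) == n)
  }
  preds <- if (is_classifier(spec))
    factor(rep(NA_character_, n), levels = levels(y), ordered = is.ordered(y))
  else numeric(n)
  n_const <- 0L
  for (f in unique(folds)) {
    tr <- folds != f
    if (is.numeric(y) && stats::var(y[tr]) == 0) n_const <- n_const + 1L
    model <- fit_one(spec, X[tr, , drop = FALSE], y[tr])
    preds[!tr] <- model(X[!tr, , drop = FALSE])
  }
  if (n_const > 0L)
    warning("constant target in ", n_const,
            " training fold(s); intercept-only fit")
  attr(preds, "folds") <- folds
  preds
}

cv_rmse <- function(spec, X, y, k, seed, folds = NULL) {
  rmse(y, as.numeric(cv_predict(spec, X, y, k = k, seed = seed,
                                folds = folds)))
}

#' Greedy wrapper feature selection
#'
#' Scores candidate feature subsets by the out-of-fold RMSE of one model
#' family ("wrapper" selection). Forward selection starts from the empty
#' set (the mean-only model) and adds the feature giving the largest RMSE
#' improvement, stopping when the best improvement is `<= tol`. Backward
#' elimination starts from the full set and removes the feature whose
#' removal most improves (or least harms) the RMSE, stopping when the best
#' removal would worsen it by more than `tol`. Ties are broken toward the
#' lexicographically smallest feature name. The fold assignment is fixed
#' once per run, so all candidate subsets are scored on identical splits.
#'
#' @param X Feature table (columns = candidate features).
#' @param y Numeric target.
#' @param spec Regression [model_spec()] used as the wrapped learner.
#' @param direction `"forward"` or `"backward"`.
#' @param k,seed Cross-validation folds and seed.
#' @param tol Minimum improvement to continue (default 1e-4 RMSE).
#' @param max_features Optional cap on the selected-set size (forward only).
#' @return Object of class `selection_result`: `direction`, `selected`
#'   (ordered feature names), `objective` (final CV RMSE), `steps`
#'   (accepted-step summary) and `trajectory` (every evaluated candidate:
#'   step, action, feature, objective).
#' @export
wrapper_select <- function(X, y, spec = model_spec("svr"),
                           direction = c("forward", "backward"),
                           k = 10L, seed = 1L, tol = 1e-4,
                           max_features = Inf) {
  direction <- match.arg(direction)
  stopifnot(!is_classifier(spec))
  X <- as.data.frame(X)
  feats <- sort(names(X))
  stopifnot(length(feats) >= 1L)
  folds <- cv_folds(nrow(X), k, seed)
  score_set <- function(s) {
    if (length(s) == 0L) {
      # mean-only model, still out-of-fold
      preds <- numeric(length(y))
      for (f in unique(folds)) preds[folds == f] <- mean(y[folds != f])
      return(rmse(y, preds))
    }
    cv_rmse(spec, X[, s, drop = FALSE], y, k = k, seed = seed, folds = folds)
  }
  current <- if (direction == "forward") character(0) else feats
  obj <- score_set(current)
  traj <- list(); steps <- list(); step <- 0L
  repeat {
    cands <- if (direction == "forward") setdiff(feats, current) else current
    if (length(cands) == 0L) break
    if (direction == "forward" && length(current) >= max_features) break
    step <- step + 1L
    objs <- vapply(cands, function(f) {
      s <- if (direction == "forward") c(current, f) else setdiff(current, f)
      score_set(s)
    }, numeric(1))
    traj[[step]] <- data.frame(
      step = step,
      action = if (direction == "forward") "add" else "remove",
      feature = cands, objective = unname(objs), row.names = NULL)
    best <- which.min(objs)  # cands sorted -> lexicographic tie-break
    accept <- if (direction == "forward") obj - objs[best] > tol
              else objs[best] <= obj + tol
    if (!accept) break
    current <- if (direction == "forward") c(current, cands[best])
               else setdiff(current, cands[best])
    steps[[step]] <- data.frame(
      step = step,
      action = if (direction == "forward") "add" else "remove",
      feature = cands[best], objective = unname(objs[best]))
    obj <- unname(objs[best])
    if (direction == "backward" && length(current) == 0L) break
  }
  structure(list(direction = direction, selected = current, objective = obj,
                 steps = do.call(rbind, steps),
                 trajectory = do.call(rbind, traj)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("wrapper %s selection: %d feature(s), CV RMSE %.4f\n",
              x$direction, length(x$selected), x$objective))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a final model on selected features
#'
#' @param spec A [model_spec()].
#' @param X Feature table.
#' @param y Target.
#' @param selected Non-empty character vector of feature names (must be
#'   columns of `X`).
#' @return Object of class `pain_model` supporting [predict()] on new
#'   tables carrying the selected columns.
#' @export
fit_final <- function(spec, X, y, selected = names(as.data.frame(X))) {
  X <- as.data.frame(X)
  stopifnot(length(selected) >= 1L)
  missing_cols <- setdiff(selected, names(X))
  if (length(missing_cols))
    stop("missing selected feature(s): ", paste(missing_cols, collapse = ", "))
  model <- fit_one(spec, X[, selected, drop = FALSE], y)
  structure(list(spec = spec, selected = selected, predict_fun = model),
            class = "pain_model")
}

#' @export
predict.pain_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$selected, names(newdata))
  if (length(missing_cols))
    stop("missing selected feature(s): ", paste(missing_cols, collapse = ", "))
  object$predict_fun(newdata[, object$selected, drop = FALSE])
}
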