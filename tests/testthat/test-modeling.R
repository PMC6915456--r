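# small linear-truth fixture
linear_data <- function(seed, n = 60, p = 4, beta1 = 2, noise = 0) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("f", seq_len(p)))))
  y <- beta1 * X$f1 + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("out-of-fold predictions cover each sample exactly once", {
  d <- linear_data(1, n = 30)
  pred <- cv_predict(model_spec("ridge", lambda = 0.01), d$X, d$y,
                     k = 5, seed = 2)
  expect_length(as.numeric(pred), 30L)
  folds <- attr(pred, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  # leave-one-out at the k = n boundary
  d2 <- linear_data(2, n = 12)
  p2 <- cv_predict(model_spec("ridge", lambda = 0.01), d2$X, d2$y,
                   k = 12, seed = 1)
  expect_length(as.numeric(p2), 12L)
  expect_error(cv_predict(model_spec("ridge"), d2$X, d2$y, k = 13, seed = 1))
})

test_that("near-noiseless linear truth is recovered by lightly penalised ridge", {
  d <- linear_data(3, n = 80, noise = 0.01)
  pred <- cv_predict(model_spec("ridge", lambda = 1e-4), d$X, d$y,
                     k = 10, seed = 4)
  expect_lt(rmse(d$y, as.numeric(pred)), 0.05 * pop_sd(d$y))
})

test_that("cross-validation is deterministic given the seed", {
  d <- linear_data(5, n = 40, noise = 0.5)
  for (fam in c("ridge", "lasso", "svr", "gpr")) {
    a <- cv_predict(model_spec(fam), d$X, d$y, k = 5, seed = 9)
    b <- cv_predict(model_spec(fam), d$X, d$y, k = 5, seed = 9)
    expect_identical(a, b, info = fam)
  }
})

test_that("missing feature values are refused", {
  d <- linear_data(6, n = 20)
  d$X$f1[3] <- NA
  expect_error(cv_predict(model_spec("ridge"), d$X, d$y, k = 4, seed = 1),
               "missing")
})

test_that("forward selection equals an exhaustive greedy oracle", {
  spec <- model_spec("ridge", lambda = 0.1)
  for (seed in 1:4) {
    set.seed(seed)
    n <- 36; p <- 5
    X <- as.data.frame(matrix(rnorm(n * p), n,
                              dimnames = list(NULL, paste0("f", 1:p))))
    y <- 2 * X$f1 - 1.5 * X$f3 + rnorm(n, 0, 0.3)
    k <- 4; cvseed <- 100 + seed; tol <- 1e-4

    sel <- wrapper_select(X, y, spec, "forward", k = k, seed = cvseed,
                          tol = tol)

    # independent greedy: enumerate every candidate addition per step
    folds <- cv_folds(n, k, cvseed)
    score <- function(s) {
      if (!length(s)) {
        pr <- numeric(n)
        for (f in unique(folds)) pr[folds == f] <- mean(y[folds != f])
        return(sqrt(mean((y - pr)^2)))
      }
      pr <- as.numeric(cv_predict(spec, X[, s, drop = FALSE], y,
                                  folds = folds))
      sqrt(mean((y - pr)^2))
    }
    cur <- character(0); best <- score(cur)
    repeat {
      cands <- sort(setdiff(names(X), cur))
      if (!length(cands)) break
      objs <- vapply(cands, function(f) score(c(cur, f)), numeric(1))
      if (best - min(objs) <= tol) break
      cur <- c(cur, cands[which.min(objs)]); best <- min(objs)
    }
    expect_identical(sel$selected, cur, info = paste("seed", seed))
    expect_equal(sel$objective, best)
  }
})

test_that("a single feature is selected iff it beats the mean-only model", {
  set.seed(8)
  n <- 40
  strong <- data.frame(f1 = rnorm(n))
  y_strong <- 3 * strong$f1
  sel <- wrapper_select(strong, y_strong, model_spec("ridge", lambda = 0.01),
                        "forward", k = 5, seed = 1)
  expect_identical(sel$selected, "f1")

  pure_noise <- data.frame(f1 = rnorm(n))
  y_noise <- rnorm(n)
  sel2 <- wrapper_select(pure_noise, y_noise, model_spec("ridge", lambda = 10),
                         "forward", k = 5, seed = 1, tol = 0.05)
  expect_length(sel2$selected, 0L)
})

test_that("selection never ends worse than the full feature set", {
  d <- linear_data(9, n = 50, noise = 0.5)
  spec <- model_spec("ridge", lambda = 0.1)
  folds <- cv_folds(50, 5, 3)
  full <- rmse(d$y, as.numeric(cv_predict(spec, d$X, d$y, folds = folds)))
  for (dir in c("forward", "backward")) {
    sel <- wrapper_select(d$X, d$y, spec, dir, k = 5, seed = 3, tol = 1e-4)
    expect_lte(sel$objective, full + 1e-4)
    if (dir == "forward" && !is.null(sel$steps))
      expect_true(all(diff(sel$steps$objective) <= 0))
  }
})

test_that("fitted models predict and guard their feature contract", {
  d <- linear_data(10, n = 50, noise = 0.2)
  fit <- fit_final(model_spec("ridge", lambda = 0.01), d$X, d$y,
                   selected = c("f1", "f2"))
  pr <- predict(fit, d$X)
  expect_lt(rmse(d$y, pr), 0.5)
  expect_error(predict(fit, d$X[c("f2", "f3")]), "f1")
  expect_error(fit_final(model_spec("ridge"), d$X, d$y, selected = "nope"),
               "nope")
  # overwhelming regularisation collapses to the target mean
  flat <- fit_final(model_spec("ridge", lambda = 1e7), d$X, d$y)
  expect_equal(unname(predict(flat, d$X)), rep(mean(d$y), 50),
               tolerance = 1e-2)
})

test_that("constant training targets fall back to intercept-only fits", {
  X <- data.frame(f1 = rnorm(20))
  y <- rep(5, 20)
  expect_warning(pred <- cv_predict(model_spec("ridge"), X, y, k = 4,
                                    seed = 1), "constant")
  expect_equal(unname(as.numeric(pred)), rep(5, 20))
})

test_that("the SVM route demands a factor and stratifies folds", {
  set.seed(13)
  X <- data.frame(f1 = c(rnorm(40, -2), rnorm(40, 2)))
  y <- categorize(c(runif(40, 0, 3), runif(40, 7, 10)))
  pred <- cv_predict(model_spec("svm"), X, y, k = 5, seed = 2)
  expect_s3_class(pred, "factor")
  expect_equal(levels(pred), pain_levels())
  rep_ <- classification_report(y, pred)
  expect_gt(rep_$accuracy, 0.8)
})

test_that("every family beats the mean-only baseline when signal exists", {
  fams <- c("ridge", "lasso", "gpr", "svr")
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80
    X <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
    y <- 2 * X$f1 + rnorm(n, 0, 0.5)
    base <- pop_sd(y)
    for (fam in fams) {
      oof <- rmse(y, as.numeric(cv_predict(model_spec(fam), X, y,
                                           k = 10, seed = seed)))
      expect_lte(oof, base + 0.05 * base)
    }
  }
})

test_that("kernel families dominate linear ones under a quadratic link", {
  wins <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 90
    X <- data.frame(f1 = rnorm(n))
    y <- X$f1^2 + rnorm(n, 0, 0.2)   # zero linear correlation with f1
    oof <- function(fam) rmse(y, as.numeric(
      cv_predict(model_spec(fam), X, y, k = 10, seed = seed)))
    if (min(oof("gpr"), oof("svr")) < min(oof("ridge"), oof("lasso")))
      wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})
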