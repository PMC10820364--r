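test_that("metric formulas reproduce hand-computed values and conventions", {
  # TP=3 FP=1 TN=5 FN=1, evaluated by hand from the closed forms
  yt <- c(rep(TRUE, 4), rep(FALSE, 6))
  yp <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  m <- compute_metrics(yt, yp)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 5); expect_equal(m$fn, 1)
  expect_equal(m$precision, 0.750)
  expect_equal(m$sensitivity, 0.750)
  expect_equal(m$specificity, 0.8333, tolerance = 1e-4)
  expect_equal(m$balanced_accuracy, 0.7917, tolerance = 1e-4)
  expect_equal(m$f1, 0.750)
  expect_equal(m$mcc, 0.5833, tolerance = 1e-4)
  # perfect predictions
  mp <- compute_metrics(yt, yt)
  expect_equal(unname(unlist(mp[, c("balanced_accuracy", "precision",
                                    "sensitivity", "specificity",
                                    "mcc", "f1")])),
               rep(1, 6))
  # all-negative predictions: zero-denominator conventions
  mn <- compute_metrics(yt, rep(FALSE, 10))
  expect_equal(mn$precision, 0)
  expect_equal(mn$sensitivity, 0)
  expect_equal(mn$specificity, 1)
  expect_equal(mn$mcc, 0)
})

test_that("metrics agree with a brute-force confusion oracle", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    yt <- rbinom(n, 1, runif(1)) == 1
    yp <- rbinom(n, 1, runif(1)) == 1
    m <- compute_metrics(yt, yp)
    # independent enumeration, element by element
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (yt[i] && yp[i]) tp <- tp + 1
      else if (!yt[i] && yp[i]) fp <- fp + 1
      else if (!yt[i] && !yp[i]) tn <- tn + 1
      else fn <- fn + 1
    }
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    expect_equal(unname(unlist(m[1, c("tp", "fp", "tn", "fn")])),
                 c(tp, fp, tn, fn))
    expect_equal(m$balanced_accuracy, (sens + spec) / 2)
    expect_equal(m$precision, prec); expect_equal(m$sensitivity, sens)
    expect_equal(m$specificity, spec); expect_equal(m$f1, f1)
    expect_equal(m$mcc, mcc)
  }
})

test_that("stratified split reproduces proportional counts exactly", {
  mk <- function(n, n_active) {
    tibble::tibble(compound = as.character(seq_len(n)),
                   active = seq_len(n) <= n_active)
  }
  sp <- stratified_split(mk(10, 5), 0.2, seed = 1)
  expect_equal(nrow(sp$test), 2)
  expect_equal(sum(sp$test$active), 1)          # one per class
  # partitions are disjoint and exhaustive
  expect_length(intersect(sp$train$compound, sp$test$compound), 0)
  expect_equal(sort(c(sp$train$compound, sp$test$compound)),
               sort(mk(10, 5)$compound))
  # determinism: same seed -> identical partition
  sp2 <- stratified_split(mk(10, 5), 0.2, seed = 1)
  expect_identical(sp$test$compound, sp2$test$compound)
  sp3 <- stratified_split(mk(10, 5), 0.2, seed = 2)
  expect_false(identical(sp$test$compound, sp3$test$compound))
})

test_that("cross-validation scores degenerate models correctly", {
  set.seed(4)
  n <- 120
  X <- matrix(rnorm(n * 3), n)
  y <- rep(c(TRUE, FALSE), c(30, 90))
  oracle <- function(X, y) {
    keep_y <- y
    structure(list(y = keep_y), class = "cv_oracle")
  }
  # a perfect oracle: we smuggle the fold labels through the feature matrix
  Xo <- cbind(as.numeric(y), X)
  fit_oracle <- function(X, y) structure(list(), class = "cv_oracle")
  registerS3method("predict", "cv_oracle",
                   function(object, newdata, ...) as.vector(newdata[, 1]),
                   envir = asNamespace("stats"))
  cv <- repeated_kfold_cv(Xo, y, fit_oracle, k = 4, iterations = 2, seed = 3)
  expect_true(all(cv$balanced_accuracy == 1))
  expect_true(all(cv$f1 == 1))
  # constant majority model: balanced accuracy 0.5 per fold
  fit_const <- function(X, y) structure(list(), class = "cv_const")
  registerS3method("predict", "cv_const",
                   function(object, newdata, ...) rep(0, nrow(newdata)),
                   envir = asNamespace("stats"))
  cv0 <- repeated_kfold_cv(X, y, fit_const, k = 4, iterations = 1, seed = 3)
  expect_true(all(cv0$balanced_accuracy == 0.5))
  # fold assignment depends only on the seed
  f1 <- aopqsar:::stratified_folds(y, 4, seed = 9)
  f2 <- aopqsar:::stratified_folds(y, 4, seed = 9)
  expect_identical(f1, f2)
  # summary aggregates all k x iterations folds
  expect_equal(nrow(cv), 8)
  expect_s3_class(glance(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 8 * 6)
})

test_that("in-fold oversampling and preprocessing run without leakage", {
  b <- small_split_fp()
  X <- b$fp_train$matrix[, 1:200]
  y <- b$split$train$active
  fit_fun <- function(X, y) {
    m <- build_model(model_spec("logreg", "circular_fp", seed = 1))
    train_model(m, list(X = X, y = y))
  }
  cv <- repeated_kfold_cv(X, y, fit_fun, k = 3, iterations = 1,
                          oversample_cfg = oversample_config(seed = 5), seed = 2)
  expect_equal(nrow(cv), 3)
  expect_true(all(cv$balanced_accuracy >= 0 & cv$balanced_accuracy <= 1))
})

test_that("grid search is exhaustive with the documented tie-breaks", {
  set.seed(6)
  # toy set where 1-NN memorizes the CV folds perfectly and 15-NN underfits
  X <- rbind(matrix(rnorm(40 * 2, -2), ncol = 2),
             matrix(rnorm(20 * 2, 2), ncol = 2))
  y <- rep(c(FALSE, TRUE), c(40, 20))
  factory <- function(params) {
    function(Xtr, ytr) {
      m <- build_model(model_spec("knn", "latent",
                                  hyperparameters = list(k = params$k), seed = 1))
      train_model(m, list(X = Xtr, y = ytr))
    }
  }
  gs <- grid_search(X, y, grid = list(k = c(1, 15)), factory, k = 3, seed = 2)
  expect_equal(nrow(gs$table), 2)
  direct <- vapply(c(1, 15), function(kk) {
    cv <- repeated_kfold_cv(X, y, factory(list(k = kk)), k = 3, iterations = 1,
                            seed = 2)
    s <- attr(cv, "summary"); s$mean[s$metric == "f1"]
  }, numeric(1))
  expect_equal(gs$table$mean_f1, direct)          # consistency with direct CV
  expect_equal(gs$best_params$k, c(1, 15)[which.max(direct)])
  # single-point grid returns that point
  gs1 <- grid_search(X, y, grid = list(k = 5), factory, k = 3, seed = 2)
  expect_equal(gs1$best_params$k, 5)
})

test_that("permutation importance isolates informative features", {
  set.seed(8)
  n <- 150
  signal <- rbinom(n, 1, 0.5)
  X <- cbind(signal = signal, noise = rnorm(n), const = rep(2, n))
  y <- signal == 1
  model <- new_test_linear(c(1, 0, 0), b = 0)
  imp <- permutation_importance(model, X, y, metric = "f1", repeats = 4, seed = 3)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$importance[imp$feature == "signal"], 0.2)
  expect_identical(imp$importance[imp$feature == "const"], 0)  # exact no-op
})

test_that("Shapley attributions are exact for linear models", {
  set.seed(9)
  Xb <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, c("a", "b", "c")))
  Xe <- matrix(rnorm(2 * 3), 2, dimnames = list(NULL, c("a", "b", "c")))
  w <- c(0.5, -1, 0.25)
  model <- new_test_linear(w, b = 0.1)
  sh <- shap_summary(model, Xb, Xe, seed = 1)
  base <- attr(sh, "base_value")
  pred <- attr(sh, "prediction")
  for (i in 1:2) {
    tot <- sum(sh$value[sh$row == i])
    expect_equal(base + tot, pred[i], tolerance = 1e-3)   # additivity
    # closed form for a linear model: w_j * (x_j - mean(background_j))
    expect_equal(sh$value[sh$row == i],
                 w * (Xe[i, ] - colMeans(Xb)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # constant model: all attributions zero
  model0 <- new_test_linear(c(0, 0, 0), b = 0.7)
  sh0 <- shap_summary(model0, Xb, Xe, seed = 1)
  expect_true(all(sh0$value == 0))
  # symmetry: duplicated features in a linear model share the attribution
  Xb2 <- cbind(Xb[, 1], Xb[, 1]); Xe2 <- cbind(Xe[, 1], Xe[, 1])
  model2 <- new_test_linear(c(1, 1))
  sh2 <- shap_summary(model2, Xb2, Xe2, seed = 1)
  v <- matrix(sh2$value, ncol = 2, byrow = TRUE)
  expect_equal(v[, 1], v[, 2], tolerance = 1e-10)
})
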