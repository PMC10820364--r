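# Evaluation: stratified splitting, repeated k-fold cross-validation with
# in-fold preprocessing/oversampling, grid search on F1, the six-metric
# confusion-matrix report, permutation importance, and Shapley attributions.

#' Six-metric classification report
#'
#' Computes the confusion counts and balanced accuracy, precision,
#' sensitivity, specificity, Matthews correlation coefficient and F1-score.
#' Zero-denominator cases (no predicted positives, single-class truth, ...)
#' return 0 for the affected metric.
#'
#' @param y_true,y_pred Binary vectors (logical or 0/1) of equal length.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `balanced_accuracy`,
#'   `precision`, `sensitivity`, `specificity`, `mcc`, `f1`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  yt <- as.logical(y_true); yp <- as.logical(y_pred)
  stopifnot(!anyNA(yt), !anyNA(yp))
  tp <- sum(yt & yp); fp <- sum(!yt & yp)
  tn <- sum(!yt & !yp); fn <- sum(yt & !yp)
  safe_div <- function(num, den) if (den > 0) num / den else 0
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * prec * sens, prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    balanced_accuracy = (sens + spec) / 2,
    precision = prec, sensitivity = sens, specificity = spec,
    mcc = mcc, f1 = f1
  )
}

#' Stratified train/test split
#'
#' The test size is `round(N * test_fraction)` (round half away from zero);
#' per-class test counts are the largest-remainder apportionment of the
#' class-proportional shares, so they are the nearest integers summing to the
#' test size. A class that would receive no test compound gets one, with a
#' warning.
#'
#' @param ds Data frame with an `active` column (see [aggregate_hitcalls()]).
#' @param test_fraction Fraction of compounds held out (0 < f < 0.5).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List of tibbles `train` and `test`, each carrying a `partition`
#'   attribute.
#' @export
stratified_split <- function(ds, test_fraction = 0.1, seed = 1L) {
  stopifnot(is.data.frame(ds), "active" %in% names(ds),
            test_fraction > 0, test_fraction < 0.5)
  y <- as.logical(ds$active)
  if (length(unique(y)) < 2) stop("stratified_split: both classes required")
  n <- nrow(ds)
  n_test <- as.integer(round_half_away(n * test_fraction))
  classes <- sort(unique(y))
  share <- vapply(classes, function(cl) sum(y == cl) * n_test / n, numeric(1))
  base <- floor(share)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base == 0)) {
    warning("stratified_split: class with zero test compounds; forcing 1")
    donor <- which.max(base)
    base[base == 0] <- 1
    base[donor] <- base[donor] - (sum(base) - n_test)
  }
  withr::with_seed(seed, {
    test_idx <- integer(0)
    for (ci in seq_along(classes)) {
      members <- which(y == classes[ci])
      test_idx <- c(test_idx, sample(members, base[ci]))
    }
  })
  test_idx <- sort(test_idx)
  train <- ds[-test_idx, , drop = FALSE]
  test <- ds[test_idx, , drop = FALSE]
  attr(train, "partition") <- "train"
  attr(test, "partition") <- "test"
  for (a in c("endpoint", "n_assays_used")) {
    attr(train, a) <- attr(ds, a); attr(test, a) <- attr(ds, a)
  }
  list(train = train, test = test)
}

stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      members <- sample(which(y == cl))
      fold[members] <- rep_len(seq_len(k), length(members))
    }
    fold
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Feature preprocessing (when `preprocess = TRUE`) and minority oversampling
#' (when `oversample_cfg` is given) are fitted inside each training fold
#' only; no validation-fold statistic leaks into them. A fold that ends up
#' single-class triggers a redraw with a shifted seed (logged as a message).
#'
#' @param X Feature matrix or raw `feature_bundle`.
#' @param y Binary labels.
#' @param fit_fun `function(X_train, y_train)` returning a fitted object
#'   whose `predict(object, X)` yields activity probabilities.
#' @param k Folds (default 10). @param iterations Repeats with different
#'   fold seeds (default 10).
#' @param oversample_cfg Optional [oversample_config()] applied to each
#'   training fold.
#' @param preprocess Fit [preprocess_features()] per training fold (use for
#'   descriptors/latent codes).
#' @param seed Base seed; iteration i uses `seed + i`.
#' @param threshold Probability cut for the positive class (default 0.5,
#'   predicted active when probability >= threshold).
#' @return A `cv_result`: tibble of per-fold metrics with attribute
#'   `summary` (mean and sd per metric).
#' @export
repeated_kfold_cv <- function(X, y, fit_fun, k = 10, iterations = 10,
                              oversample_cfg = NULL, preprocess = FALSE,
                              seed = 1L, threshold = 0.5) {
  stopifnot(k >= 2)
  bundle <- NULL
  if (inherits(X, "feature_bundle")) {
    bundle <- X
    X <- bundle$matrix
  }
  y <- as.logical(y)
  stopifnot(min(table(y)) >= k)
  rows <- list()
  for (it in seq_len(iterations)) {
    fold_seed <- seed + it
    repeat {
      fold <- stratified_folds(y, k, fold_seed)
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[fold == f])) == 2 && length(unique(y[fold != f])) == 2
      }, logical(1)))
      if (ok) break
      message("repeated_kfold_cv: single-class fold; redrawing (seed ",
              fold_seed, " -> ", fold_seed + 1000L, ")")
      fold_seed <- fold_seed + 1000L
    }
    for (f in seq_len(k)) {
      tr <- which(fold != f); va <- which(fold == f)
      if (!is.null(bundle) && preprocess) {
        btr <- new_feature_bundle(bundle$encoder_name,
                                  X[tr, , drop = FALSE], bundle$feature_names,
                                  bundle$compounds[tr])
        bva <- new_feature_bundle(bundle$encoder_name,
                                  X[va, , drop = FALSE], bundle$feature_names,
                                  bundle$compounds[va])
        pp <- preprocess_features(btr, bva)
        Xtr <- pp[[1]]$matrix; Xva <- pp[[2]]$matrix
      } else {
        Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
      }
      ytr <- y[tr]
      if (!is.null(oversample_cfg)) {
        cfg_f <- oversample_cfg
        cfg_f$seed <- oversample_cfg$seed + 97L * it + f
        os <- oversample(Xtr, ytr, cfg_f)
        Xtr <- os$X; ytr <- os$y
      }
      fit <- fit_fun(Xtr, ytr)
      p <- predict(fit, Xva)
      m <- compute_metrics(y[va], p >= threshold)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(iteration = it, fold = f), m)
    }
  }
  out <- dplyr::bind_rows(rows)
  metric_cols <- c("balanced_accuracy", "precision", "sensitivity",
                   "specificity", "mcc", "f1")
  summ <- tidyr::pivot_longer(out[, metric_cols], dplyr::everything(),
                              names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("cv_result", class(out))
  out
}

#' Exhaustive grid search on cross-validated F1
#'
#' Every hyperparameter combination is evaluated by stratified k-fold
#' cross-validation; the winner has the highest mean F1, ties broken by
#' higher mean balanced accuracy, then first-in-grid order.
#'
#' @param X,y Features and labels (as in [repeated_kfold_cv()]).
#' @param grid Data frame of hyperparameter combinations (one row each) or a
#'   named list of value vectors to be crossed.
#' @param fit_factory `function(params)` returning a
#'   `fit_fun(X_train, y_train)`.
#' @param k Folds (default 5). @param seed Seed shared by all grid points so
#'   every combination sees identical folds.
#' @param oversample_cfg,preprocess Passed through to the CV.
#' @return List: `best_params` (one-row tibble), `table` (per-combination
#'   mean F1 and balanced accuracy).
#' @export
grid_search <- function(X, y, grid, fit_factory, k = 5, seed = 1L,
                        oversample_cfg = NULL, preprocess = FALSE) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid, stringsAsFactors = FALSE)
  stopifnot(nrow(grid) >= 1)
  res <- purrr::map(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    cv <- repeated_kfold_cv(X, y, fit_factory(params), k = k, iterations = 1,
                            oversample_cfg = oversample_cfg,
                            preprocess = preprocess, seed = seed)
    s <- attr(cv, "summary")
    tibble::tibble(
      grid_row = i,
      mean_f1 = s$mean[s$metric == "f1"],
      mean_balanced_accuracy = s$mean[s$metric == "balanced_accuracy"]
    )
  }) |> dplyr::bind_rows()
  ord <- order(-res$mean_f1, -res$mean_balanced_accuracy, res$grid_row)
  best <- ord[1]
  list(best_params = tibble::as_tibble(grid[best, , drop = FALSE]),
       table = dplyr::bind_cols(tibble::as_tibble(grid), res[, -1]))
}

#' Permutation feature importance
#'
#' Importance of a feature = baseline metric minus the metric after randomly
#' permuting that feature column, averaged over `repeats` independent
#' shuffles. Shuffling a constant column is a no-op, so its importance is
#' exactly zero.
#'
#' @param model Fitted object with a probability `predict` method.
#' @param X,y Evaluation features and labels.
#' @param metric `"f1"` or `"balanced_accuracy"`.
#' @param repeats Shuffle repeats per feature (default 5).
#' @param seed Integer seed. @param threshold Probability cut (default 0.5).
#' @return Tibble: `feature`, `importance` (mean), `sd`, sorted decreasing.
#' @export
permutation_importance <- function(model, X, y, metric = c("f1", "balanced_accuracy"),
                                   repeats = 5, seed = 1L, threshold = 0.5) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  y <- as.logical(y)
  score <- function(Xe) {
    m <- compute_metrics(y, predict(model, Xe) >= threshold)
    m[[metric]]
  }
  base <- score(X)
  nm <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  withr::with_seed(seed, {
    imp <- purrr::map(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        base - score(Xp)
      }, numeric(1))
      tibble::tibble(feature = nm[j], importance = mean(drops),
                     sd = stats::sd(drops))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::arrange(imp, dplyr::desc(.data$importance))
  attr(out, "baseline") <- base
  class(out) <- c("importance_result", class(out))
  out
}

#' Shapley feature attributions
#'
#' Interventional Shapley values of the model's predicted probability:
#' exact subset enumeration for up to `exact_limit` features, Monte-Carlo
#' permutation sampling beyond that. Attributions satisfy additivity:
#' base value + row sum equals the model output (exactly in the enumeration
#' regime).
#'
#' @param model Fitted object with a probability `predict` method.
#' @param X_background Background matrix defining the reference distribution
#'   (subsampled to at most `max_background` rows).
#' @param X_explain Rows to explain.
#' @param exact_limit Feature count up to which exact enumeration is used
#'   (default 12).
#' @param nsim Permutations per row for the Monte-Carlo regime.
#' @param max_background Background subsample cap (default 50).
#' @param seed Integer seed.
#' @return A `shap_result` tibble (row, feature, value) with attributes
#'   `base_value` and `prediction`.
#' @export
shap_summary <- function(model, X_background, X_explain, exact_limit = 12,
                         nsim = 200, max_background = 50, seed = 1L) {
  X_background <- as.matrix(X_background)
  X_explain <- as.matrix(X_explain)
  p <- ncol(X_explain)
  stopifnot(ncol(X_background) == p)
  nm <- colnames(X_explain) %||% paste0("f", seq_len(p))
  withr::with_seed(seed, {
    if (nrow(X_background) > max_background) {
      X_background <- X_background[sample(nrow(X_background), max_background), ,
                                   drop = FALSE]
    }
    base_value <- mean(predict(model, X_background))
    phi <- if (p <= exact_limit) {
      shap_exact(model, X_background, X_explain)
    } else {
      shap_sample(model, X_background, X_explain, nsim)
    }
  })
  pred <- predict(model, X_explain)
  out <- tibble::tibble(
    row = rep(seq_len(nrow(X_explain)), each = p),
    feature = rep(nm, nrow(X_explain)),
    value = as.vector(t(phi))
  )
  attr(out, "base_value") <- base_value
  attr(out, "prediction") <- pred
  class(out) <- c("shap_result", class(out))
  out
}

# exact interventional Shapley by subset enumeration
shap_exact <- function(model, Xb, Xe) {
  p <- ncol(Xe)
  nb <- nrow(Xb)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  # value of each subset S for each explain row: E_b f(x_S, b_~S)
  vals <- matrix(0, nrow(subsets), nrow(Xe))
  for (s in seq_len(nrow(subsets))) {
    S <- subsets[s, ]
    for (i in seq_len(nrow(Xe))) {
      Xmix <- Xb
      if (any(S)) Xmix[, S] <- matrix(Xe[i, S], nb, sum(S), byrow = TRUE)
      vals[s, i] <- mean(predict(model, Xmix))
    }
  }
  sizes <- rowSums(subsets)
  key <- apply(subsets, 1, paste, collapse = "")
  lookup <- stats::setNames(seq_len(nrow(subsets)), key)
  phi <- matrix(0, nrow(Xe), p)
  for (j in seq_len(p)) {
    without_j <- which(!subsets[, j])
    for (s in without_j) {
      S <- subsets[s, ]
      Sj <- S; Sj[j] <- TRUE
      s2 <- lookup[[paste(Sj, collapse = "")]]
      w <- factorial(sizes[s]) * factorial(p - sizes[s] - 1) / factorial(p)
      phi[, j] <- phi[, j] + w * (vals[s2, ] - vals[s, ])
    }
  }
  phi
}

# Monte-Carlo permutation sampling (one background row per permutation)
shap_sample <- function(model, Xb, Xe, nsim) {
  p <- ncol(Xe)
  phi <- matrix(0, nrow(Xe), p)
  for (i in seq_len(nrow(Xe))) {
    acc <- numeric(p)
    for (s in seq_len(nsim)) {
      perm <- sample(p)
      b <- Xb[sample(nrow(Xb), 1), ]
      x_cur <- b
      prev <- predict(model, matrix(x_cur, 1))
      for (j in perm) {
        x_cur[j] <- Xe[i, j]
        cur <- predict(model, matrix(x_cur, 1, dimnames = list(NULL, colnames(Xe))))
        acc[j] <- acc[j] + (cur - prev)
        prev <- cur
      }
    }
    phi[i, ] <- acc / nsim
  }
  phi
}
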