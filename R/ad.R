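# Applicability domain: five methods fitted on training features only
# (bounding box, bounding box on principal components, leverage, distance
# from centroid, variable-k nearest-neighbour distance), and the
# all-methods x all-encoders discard consensus.

AD_METHODS <- c("bounding_box", "bounding_box_pca", "leverage",
                "centroid_distance", "knn_variable_k")

#' Fit an applicability-domain model
#'
#' @param X_train Numeric training matrix or a `feature_bundle`.
#' @param method One of `"bounding_box"`, `"bounding_box_pca"`, `"leverage"`,
#'   `"centroid_distance"`, `"knn_variable_k"`.
#' @param params Optional list of method parameters: `pca_variance`
#'   (explained-variance cut for the PCA box, default 0.95),
#'   `leverage_factor` (threshold multiplier `factor * p / n`, default 3),
#'   `k` (neighbour count for the kNN method; default `round(n^(1/3))`),
#'   `knn_quantile` (calibration quantile of training neighbour distances,
#'   default 0.95), `ridge` (fallback regularization for a singular
#'   cross-product in the leverage method, default 1e-8).
#' @return An `ad_model`.
#' @export
fit_ad <- function(X_train, method = AD_METHODS, params = list()) {
  method <- match.arg(method)
  if (inherits(X_train, "feature_bundle")) {
    encoder <- X_train$encoder_name
    X_train <- X_train$matrix
  } else {
    encoder <- attr(X_train, "encoder_name") %||% NA_character_
  }
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 3) stop("fit_ad: need at least 3 training compounds")
  if (anyNA(X_train)) stop("fit_ad: training matrix contains NA; preprocess first")
  p <- ncol(X_train)
  fitted <- switch(method,
    bounding_box = list(
      min = apply(X_train, 2, min), max = apply(X_train, 2, max)
    ),
    bounding_box_pca = {
      pv <- params$pca_variance %||% 0.95
      pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      k <- max(1L, which(cum >= pv)[1])
      scores <- pc$x[, seq_len(k), drop = FALSE]
      list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
           min = apply(scores, 2, min), max = apply(scores, 2, max),
           n_components = k)
    },
    leverage = {
      ridge <- params$ridge %||% 1e-8
      XtX <- crossprod(X_train)
      inv <- tryCatch(solve(XtX), error = function(e) {
        solve(XtX + diag(ridge * mean(diag(XtX)), p))
      })
      list(inv_xtx = inv, n = nrow(X_train), p = p,
           threshold = (params$leverage_factor %||% 3) * p / nrow(X_train))
    },
    centroid_distance = {
      ctr <- colMeans(X_train)
      d <- sqrt(rowSums(sweep(X_train, 2, ctr)^2))
      list(centroid = ctr, threshold = max(d))
    },
    knn_variable_k = {
      n <- nrow(X_train)
      k <- params$k %||% max(1L, round(n^(1 / 3)))
      k <- min(k, n - 1L)
      nn <- knn_index(X_train, X_train, k = k + 1L, exclude_self = FALSE)
      self_d <- vapply(seq_len(n), function(i) {
        ids <- setdiff(nn[i, ], i)[seq_len(k)]
        mean(sqrt(rowSums(sweep(X_train[ids, , drop = FALSE], 2, X_train[i, ])^2)))
      }, numeric(1))
      list(X = X_train, k = k,
           threshold = stats::quantile(self_d, params$knn_quantile %||% 0.95,
                                       names = FALSE))
    }
  )
  structure(list(method = method, encoder = encoder, p = p, fitted = fitted),
            class = "ad_model")
}

#' @exportS3Method base::print
print.ad_model <- function(x, ...) {
  cat("<ad_model>", x$method, "on", x$p, "features",
      if (!is.na(x$encoder)) paste0("(encoder: ", x$encoder, ")"), "\n")
  invisible(x)
}

#' Assess whether query compounds fall inside a fitted domain
#'
#' @param ad An `ad_model` from [fit_ad()].
#' @param X_query Numeric matrix (or `feature_bundle`) in the same feature
#'   space the model was fitted on.
#' @return Logical vector, `TRUE` = in domain.
#' @export
assess <- function(ad, X_query) {
  stopifnot(inherits(ad, "ad_model"))
  if (inherits(X_query, "feature_bundle")) X_query <- X_query$matrix
  X_query <- as.matrix(X_query)
  if (ncol(X_query) != ad$p) {
    stop("assess: query has ", ncol(X_query), " features, model expects ", ad$p)
  }
  f <- ad$fitted
  switch(ad$method,
    bounding_box = {
      apply(X_query, 1, function(r) all(r >= f$min & r <= f$max))
    },
    bounding_box_pca = {
      S <- sweep(X_query, 2, f$center) %*% f$rotation
      apply(S, 1, function(r) all(r >= f$min & r <= f$max))
    },
    leverage = {
      h <- rowSums((X_query %*% f$inv_xtx) * X_query)
      h <= f$threshold
    },
    centroid_distance = {
      d <- sqrt(rowSums(sweep(X_query, 2, f$centroid)^2))
      d <= f$threshold
    },
    knn_variable_k = {
      nn <- knn_index(f$X, X_query, k = f$k, exclude_self = FALSE)
      d <- vapply(seq_len(nrow(X_query)), function(i) {
        ids <- nn[i, ]
        mean(sqrt(rowSums(sweep(f$X[ids, , drop = FALSE], 2, X_query[i, ])^2)))
      }, numeric(1))
      d <= f$threshold
    }
  )
}

training_leverages <- function(ad_leverage, X_train) {
  stopifnot(ad_leverage$method == "leverage")
  rowSums((as.matrix(X_train) %*% ad_leverage$fitted$inv_xtx) * as.matrix(X_train))
}

#' Run the applicability-domain consensus across methods and encoders
#'
#' Fits every method on every (tabular) encoder's training features, assesses
#' the query compounds, and applies the discard rule: a compound is discarded
#' only when it is out of domain under every method of every encoder.
#'
#' @param train_bundles Named list of training `feature_bundle`s (tabular
#'   encoders: descriptors, fingerprints, latent codes).
#' @param query_bundles Named list of query `feature_bundle`s over the same
#'   encoders.
#' @param methods AD methods to use (default: all five).
#' @param params Optional per-method parameter list passed to [fit_ad()].
#' @return List: `verdicts` (tidy tibble: compound index, encoder, method,
#'   `in_domain`) and `consensus` (tibble: compound index, `keep`).
#' @export
ad_consensus <- function(train_bundles, query_bundles,
                         methods = AD_METHODS, params = list()) {
  stopifnot(length(train_bundles) >= 1, length(methods) >= 1)
  stopifnot(identical(sort(names(train_bundles)), sort(names(query_bundles))))
  verdicts <- purrr::map(names(train_bundles), function(enc) {
    purrr::map(methods, function(m) {
      ad <- fit_ad(train_bundles[[enc]], m, params)
      tibble::tibble(
        compound = seq_len(nrow(query_bundles[[enc]]$matrix)),
        encoder = enc, method = m,
        in_domain = assess(ad, query_bundles[[enc]])
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  consensus <- verdicts |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(keep = any(.data$in_domain), .groups = "drop")
  list(verdicts = verdicts, consensus = consensus)
}

#' Consensus keep/discard from a tidy verdict table
#'
#' @param verdicts Tibble with columns `compound` and `in_domain` (typically
#'   also `method` and `encoder`).
#' @return Tibble: `compound`, `keep` (`FALSE` only when out of domain under
#'   every method and every encoder).
#' @export
consensus_keep <- function(verdicts) {
  stopifnot(all(c("compound", "in_domain") %in% names(verdicts)))
  verdicts |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(keep = any(.data$in_domain), .groups = "drop")
}
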