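# Minority-class oversampling: SMOTE and its Borderline-1/2, SVM and k-means
# variants, restricted by the evaluation module to training folds, plus a
# per-feature distribution-shift report.

#' Oversampling configuration
#'
#' @param variant One of `"smote"`, `"borderline1"`, `"borderline2"`,
#'   `"svm_smote"`, `"kmeans_smote"`.
#' @param k_neighbors Nearest-neighbour count used for interpolation
#'   (default 5).
#' @param seed Integer seed.
#' @param target_ratio Minority/majority ratio after resampling (default 1).
#' @return An `oversample_config` list.
#' @export
oversample_config <- function(variant = c("smote", "borderline1", "borderline2",
                                          "svm_smote", "kmeans_smote"),
                              k_neighbors = 5L, seed = 1L, target_ratio = 1) {
  variant <- match.arg(variant)
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(variant = variant, k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed), target_ratio = target_ratio),
            class = "oversample_config")
}

knn_index <- function(X, query = X, k, exclude_self = FALSE) {
  # pairwise Euclidean distances; data sizes here are training folds, so the
  # dense matrix is fine
  d2 <- outer(rowSums(query^2), rowSums(X^2), "+") - 2 * query %*% t(X)
  d2[d2 < 0] <- 0
  k_eff <- min(k, ncol(d2) - exclude_self)
  res <- vapply(seq_len(nrow(query)), function(i) {
    ord <- order(d2[i, ])
    if (exclude_self) ord <- ord[ord != i]
    ord[seq_len(k_eff)]
  }, integer(k_eff))
  if (k_eff == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Oversample the minority class (SMOTE family)
#'
#' Synthetic minority rows are drawn on the segment between a minority seed
#' point and one of its k nearest minority neighbours:
#' `x_new = x_i + u * (x_nn - x_i)`, `u ~ U(0, 1)`. Variants change which
#' points seed the interpolation: Borderline-1/2 use minority points whose
#' neighbourhood is majority-dominated (but not entirely majority);
#' SVM-SMOTE seeds from minority support vectors of an SVM decision boundary;
#' k-means-SMOTE seeds within minority-dominated k-means clusters. Original
#' rows are always preserved verbatim.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (logical or 0/1), same length as `nrow(X)`.
#' @param cfg An [oversample_config()].
#' @return List: `X` (original rows first, synthetic rows appended), `y`,
#'   `synthetic` (logical index into the returned rows).
#' @export
oversample <- function(X, y, cfg = oversample_config()) {
  stopifnot(inherits(cfg, "oversample_config"))
  X <- as.matrix(X)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y))
  classes <- table(y)
  if (length(classes) < 2L) stop("oversample: single-class input")
  minority <- names(classes)[which.min(classes)] == "TRUE"
  n_min <- min(classes); n_maj <- max(classes)
  if (n_min <= cfg$k_neighbors) {
    stop("oversample: minority class has ", n_min, " rows but the '",
         cfg$variant, "' variant needs more than k_neighbors = ",
         cfg$k_neighbors)
  }
  n_target <- round(cfg$target_ratio * n_maj) - n_min
  if (n_target <= 0L) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  Xmin <- X[y == minority, , drop = FALSE]
  Xmaj <- X[y != minority, , drop = FALSE]

  withr::with_seed(cfg$seed, {
    seeds_idx <- switch(cfg$variant,
      smote = seq_len(nrow(Xmin)),
      borderline1 = ,
      borderline2 = borderline_seeds(Xmin, Xmaj, cfg$k_neighbors),
      svm_smote = svm_seeds(Xmin, Xmaj),
      kmeans_smote = kmeans_seeds(Xmin, Xmaj, cfg$k_neighbors)
    )
    if (!length(seeds_idx)) seeds_idx <- seq_len(nrow(Xmin))  # fall back to plain smote
    nn <- knn_index(Xmin, Xmin[seeds_idx, , drop = FALSE],
                    k = cfg$k_neighbors, exclude_self = FALSE)
    # neighbour search runs within the minority class; drop self matches
    pick_seed <- sample(seq_along(seeds_idx), n_target, replace = TRUE)
    synth <- matrix(0, n_target, ncol(X))
    for (s in seq_len(n_target)) {
      i <- seeds_idx[pick_seed[s]]
      cand <- setdiff(nn[pick_seed[s], ], i)
      j <- if (length(cand)) sample(cand, 1) else i
      u <- stats::runif(1)
      if (cfg$variant == "borderline2") u <- u / 2  # pull towards the seed
      synth[s, ] <- Xmin[i, ] + u * (Xmin[j, ] - Xmin[i, ])
    }
    colnames(synth) <- colnames(X)
    list(
      X = rbind(X, synth),
      y = c(y, rep(minority, n_target)),
      synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_target))
    )
  })
}

# minority points whose k-neighbourhood (in the full set) is majority-
# dominated but not purely majority ("danger" points)
borderline_seeds <- function(Xmin, Xmaj, k) {
  Xall <- rbind(Xmin, Xmaj)
  lab <- c(rep(TRUE, nrow(Xmin)), rep(FALSE, nrow(Xmaj)))
  nn <- knn_index(Xall, Xmin, k = k + 1, exclude_self = FALSE)
  vapply(seq_len(nrow(Xmin)), function(i) {
    ids <- setdiff(nn[i, ], i)[seq_len(min(k, ncol(nn) - 1))]
    n_maj <- sum(!lab[ids])
    n_maj >= length(ids) / 2 && n_maj < length(ids)
  }, logical(1)) |> which()
}

svm_seeds <- function(Xmin, Xmaj) {
  Xall <- rbind(Xmin, Xmaj)
  yall <- factor(c(rep("min", nrow(Xmin)), rep("maj", nrow(Xmaj))))
  fit <- e1071::svm(Xall, yall, kernel = "linear", scale = FALSE)
  sv <- fit$index[fit$index <= nrow(Xmin)]
  sv
}

kmeans_seeds <- function(Xmin, Xmaj, k) {
  Xall <- rbind(Xmin, Xmaj)
  lab <- c(rep(TRUE, nrow(Xmin)), rep(FALSE, nrow(Xmaj)))
  nc <- max(2L, min(8L, nrow(Xall) %/% 10L))
  cl <- stats::kmeans(Xall, centers = nc, nstart = 3)$cluster
  keep <- which(vapply(seq_len(nc), function(c_) {
    mean(lab[cl == c_]) > 0.5
  }, logical(1)))
  which(lab[seq_len(nrow(Xmin))] & cl[seq_len(nrow(Xmin))] %in% keep)
}

#' Distribution-shift report after resampling
#'
#' Per feature: mean and standard deviation of the original and resampled
#' sets plus the two-sample Kolmogorov-Smirnov statistic, with a flag where
#' the KS statistic exceeds `threshold`.
#'
#' @param X_orig,X_resampled Feature matrices over the same feature space.
#' @param threshold Flag threshold on the KS statistic (default 0.2).
#' @return Tibble, one row per feature; attribute `any_flagged`.
#' @export
distribution_shift_report <- function(X_orig, X_resampled, threshold = 0.2) {
  X_orig <- as.matrix(X_orig); X_resampled <- as.matrix(X_resampled)
  stopifnot(ncol(X_orig) == ncol(X_resampled))
  nm <- colnames(X_orig) %||% paste0("f", seq_len(ncol(X_orig)))
  rows <- purrr::map(seq_len(ncol(X_orig)), function(j) {
    a <- X_orig[, j]; b <- X_resampled[, j]
    ks <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
      0
    } else {
      suppressWarnings(unname(stats::ks.test(a, b)$statistic))
    }
    tibble::tibble(
      feature = nm[j],
      mean_orig = mean(a), sd_orig = stats::sd(a),
      mean_resampled = mean(b), sd_resampled = stats::sd(b),
      ks_statistic = ks,
      flagged = ks > threshold
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "any_flagged") <- any(out$flagged)
  out
}
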