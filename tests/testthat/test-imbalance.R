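test_that("synthetic rows satisfy the segment identity and equalize counts", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40 * 3, mean = 0), ncol = 3),
             matrix(rnorm(10 * 3, mean = 3), ncol = 3))
  y <- rep(c(FALSE, TRUE), c(40, 10))
  os <- oversample(X, y, oversample_config("smote", k_neighbors = 3, seed = 2))
  expect_equal(sum(os$y), sum(!os$y))                 # ratio 1 reached
  expect_equal(os$X[1:50, ], X)                       # originals verbatim
  # convex-combination identity within 1e-9: each synthetic row lies on a
  # segment between two minority rows -> interpolation weights agree across
  # coordinates
  Xmin <- X[y, , drop = FALSE]
  for (s in which(os$synthetic)) {
    z <- os$X[s, ]
    found <- FALSE
    for (i in seq_len(nrow(Xmin))) for (j in seq_len(nrow(Xmin))) {
      d <- Xmin[j, ] - Xmin[i, ]
      if (all(abs(d) < 1e-12)) next
      u <- (z - Xmin[i, ])[which.max(abs(d))] / d[which.max(abs(d))]
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(Xmin[i, ] + u * d - z)) < 1e-9) { found <- TRUE; break }
    }
    expect_true(found)
  }
})

test_that("two-point minority interpolation stays on the segment", {
  X <- rbind(c(0, 0), c(1, 1),
             matrix(rnorm(20, 5), ncol = 2))
  y <- c(TRUE, TRUE, rep(FALSE, 10))
  os <- oversample(X, y, oversample_config("smote", k_neighbors = 1, seed = 3))
  syn <- os$X[os$synthetic, , drop = FALSE]
  expect_true(all(abs(syn[, 1] - syn[, 2]) < 1e-9))   # both coordinates equal
  expect_true(all(syn >= -1e-9 & syn <= 1 + 1e-9))
})

test_that("balanced input comes back unchanged and errors are explicit", {
  X <- matrix(rnorm(40), ncol = 2)
  y <- rep(c(TRUE, FALSE), each = 10)
  os <- oversample(X, y)
  expect_equal(os$X, X)
  expect_false(any(os$synthetic))
  expect_error(oversample(X, rep(TRUE, 20)), "single-class")
  expect_error(oversample(X, c(TRUE, rep(FALSE, 19)),
                          oversample_config(k_neighbors = 5)),
               "k_neighbors")
})

test_that("oversampling is reproducible and every variant reaches balance", {
  set.seed(7)
  X <- rbind(matrix(rnorm(120 * 4), ncol = 4),
             matrix(rnorm(30 * 4, mean = 2.5), ncol = 4))
  y <- rep(c(FALSE, TRUE), c(120, 30))
  for (v in c("smote", "borderline1", "borderline2", "svm_smote", "kmeans_smote")) {
    cfg <- oversample_config(v, k_neighbors = 5, seed = 11)
    os1 <- oversample(X, y, cfg)
    os2 <- oversample(X, y, cfg)
    expect_identical(os1, os2)
    expect_equal(sum(os1$y), sum(!os1$y))
    # synthetic points stay inside the minority bounding box (interpolation)
    syn <- os1$X[os1$synthetic, , drop = FALSE]
    Xmin <- X[y, , drop = FALSE]
    expect_true(all(syn >= matrix(apply(Xmin, 2, min), nrow(syn), 4, byrow = TRUE) - 1e-9))
    expect_true(all(syn <= matrix(apply(Xmin, 2, max), nrow(syn), 4, byrow = TRUE) + 1e-9))
  }
})

test_that("distribution-shift report flags what moved and only that", {
  set.seed(5)
  X <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("u", "v")))
  r0 <- distribution_shift_report(X, X)
  expect_equal(r0$ks_statistic, c(0, 0))
  expect_false(attr(r0, "any_flagged"))
  r1 <- distribution_shift_report(X, X + 10)
  expect_equal(r1$ks_statistic, c(1, 1))      # disjoint supports
  expect_true(all(r1$flagged))
})
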