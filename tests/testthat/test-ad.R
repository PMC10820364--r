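test_that("bounding box stores ranges and contains its training set", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  ad <- fit_ad(X, "bounding_box")
  expect_equal(unname(ad$fitted$min), 1)
  expect_equal(unname(ad$fitted$max), 3)
  expect_true(all(assess(ad, X)))                       # by construction
  expect_false(assess(ad, matrix(10, 1, 1)))
  expect_error(fit_ad(matrix(1:2, ncol = 1), "bounding_box"), "at least 3")
})

test_that("leverage diagonal sums to the feature count (hat-matrix trace)", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), ncol = 6)
  ad <- fit_ad(X, "leverage")
  h <- aopqsar:::training_leverages(ad, X)
  expect_equal(sum(h), 6, tolerance = 1e-8)
  # far query exceeds 3p/n
  expect_false(assess(ad, matrix(100, 1, 6)))
})

test_that("centroid method centres on the mean and keeps the centroid in-domain", {
  set.seed(3)
  X <- rbind(matrix(rnorm(30 * 2), ncol = 2), -matrix(rnorm(30 * 2), ncol = 2))
  ad <- fit_ad(X, "centroid_distance")
  expect_equal(ad$fitted$centroid, colMeans(X))
  expect_true(assess(ad, matrix(colMeans(X), 1)))
  expect_false(assess(ad, matrix(50, 1, 2)))
})

test_that("PCA box and variable-k kNN behave on shifted queries", {
  set.seed(4)
  X <- matrix(rnorm(60 * 4), ncol = 4)
  for (m in c("bounding_box_pca", "knn_variable_k")) {
    ad <- fit_ad(X, m)
    inside <- assess(ad, X)
    expect_gt(mean(inside), 0.8)                 # most training points inside
    expect_false(any(assess(ad, matrix(30, 2, 4))))
  }
  expect_error(assess(fit_ad(X, "bounding_box"), matrix(0, 1, 2)), "features")
})

test_that("consensus discards only all-method x all-encoder outsiders", {
  v <- tidyr::expand_grid(compound = 1:3,
                          method = aopqsar:::AD_METHODS,
                          encoder = c("descriptors", "circular_fp"))
  # compound 1: out under 4/5 methods for every encoder -> keep
  # compound 2: out under all methods of one encoder, in for the other -> keep
  # compound 3: out everywhere -> discard
  v$in_domain <- with(v, ifelse(compound == 1, method == "leverage",
                         ifelse(compound == 2, encoder == "circular_fp", FALSE)))
  ck <- consensus_keep(v)
  expect_equal(ck$keep, c(TRUE, TRUE, FALSE))
})

test_that("in-distribution queries survive; shifted queries are discarded", {
  b <- small_benchmark()
  sp <- stratified_split(b$dataset, 0.25, seed = 9)
  enc <- list(
    maccs_fp = compute_maccs_fp(sp$train),
    latent = latent_encode(sp$train, latent_encoder_hash(width = 64))
  )
  qry <- list(
    maccs_fp = compute_maccs_fp(sp$test),
    latent = latent_encode(sp$test, latent_encoder_hash(width = 64))
  )
  res <- ad_consensus(enc, qry)
  discard_rate <- mean(!res$consensus$keep)
  expect_lte(discard_rate, 0.02)       # drawn from the training distribution
  # deliberately shifted feature space: far outside every method's domain
  qry_shift <- list(
    maccs_fp = aopqsar:::new_feature_bundle(
      "maccs_fp", qry$maccs_fp$matrix + 50, qry$maccs_fp$feature_names,
      qry$maccs_fp$compounds),
    latent = aopqsar:::new_feature_bundle(
      "latent", qry$latent$matrix + 50, qry$latent$feature_names,
      qry$latent$compounds)
  )
  res2 <- ad_consensus(enc, qry_shift)
  expect_gt(mean(!res2$consensus$keep), 0.9)
  # tidy verdict table shape
  expect_setequal(names(res$verdicts), c("compound", "encoder", "method", "in_domain"))
  expect_equal(nrow(res$verdicts), nrow(sp$test) * 5 * 2)
})
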