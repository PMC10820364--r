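test_that("descriptor matrix has fixed width, deterministic rows, sane counts", {
  d <- compute_descriptors(c("C", "CCO", "CCO", "c1ccccc1C(=O)O"))
  expect_equal(ncol(d$matrix), length(descriptor_names()))
  expect_equal(d$matrix[2, ], d$matrix[3, ])          # determinism
  # methane hand counts
  expect_equal(unname(d$matrix[1, "nAtoms"]), 1)
  expect_equal(unname(d$matrix[1, "nH"]), 4)
  expect_equal(unname(d$matrix[1, "nC"]), 1)
  # benzoic acid hand counts
  ba <- d$matrix[4, ]
  expect_equal(unname(ba["nAromAtoms"]), 6)
  expect_equal(unname(ba["nCarboxyl"]), 1)
  expect_equal(unname(ba["nRings"]), 1)
  expect_equal(unname(ba["MW"]), 122.12, tolerance = 1e-3)
  # failures become NA rows, not errors
  d2 <- compute_descriptors(c("CCO", NA))
  expect_true(all(is.na(d2$matrix[2, ])))
})

test_that("circular fingerprints separate molecules by local environments", {
  fp0 <- compute_circular_fp(c("CCO", "CCC"), radius = 0, n_bits = 512)
  expect_false(all(fp0$matrix[1, ] == fp0$matrix[2, ]))  # O-centred env differs
  fp <- compute_circular_fp(c("CCO", "CCO"))
  expect_equal(ncol(fp$matrix), 2048)                    # default width
  expect_equal(fp$matrix[1, ], fp$matrix[2, ])
  expect_true(all(fp$matrix %in% 0:1))
})

test_that("MACCS keys are the documented 166-bit public set", {
  m <- compute_maccs_fp(c("c1ccccc1", "C", "c1ccccc1"))
  expect_equal(ncol(m$matrix), 166)
  expect_equal(m$matrix[1, ], m$matrix[3, ])
  # benzene sets the toolkit's aromatic-ring keys (frozen from the keyset)
  expect_setequal(which(m$matrix[1, ] == 1), c(162, 163, 165))
  # methane: only the methyl-group key fires; no hetero/ring/aromatic keys
  expect_setequal(which(m$matrix[2, ] == 1), 160)
})

test_that("molecular graphs mirror the heavy-atom structure", {
  g <- featurize_graph(c("CCO", "c1ccccc1", "C"))
  expect_equal(nrow(g[[1]]$node_features), 3)
  expect_equal(nrow(g[[1]]$edges), 2)
  expect_equal(nrow(g[[2]]$node_features), 6)
  expect_equal(nrow(g[[2]]$edges), 6)
  expect_true(all(g[[2]]$edge_features[, "conjugated"] == 1))
  expect_equal(nrow(g[[3]]$node_features), 1)
  expect_equal(nrow(g[[3]]$edges), 0)
  # node features carry the documented fields
  expect_equal(colnames(g[[1]]$node_features),
               c("atomic_number", "valence", "n_hydrogens", "hybridization"))
  expect_equal(unname(g[[1]]$node_features[3, "atomic_number"]), 8)  # oxygen
})

test_that("vocabulary building follows the nearest-rank percentile rule", {
  v <- build_vocabulary(c("CCO", "CCN"))
  expect_setequal(setdiff(v$characters, c("<pad>", "<unk>", "<s>")),
                  c("C", "O", "N"))
  corpus <- vapply(1:100, function(n) paste(rep("C", n), collapse = ""),
                   character(1))
  v2 <- build_vocabulary(corpus, length_percentile = 95)
  expect_equal(v2$output_length, 95)
  expect_error(build_vocabulary(character(0)), "empty corpus")
})

test_that("vectorization pads, truncates and maps unknowns", {
  v <- build_vocabulary(c("CCO", "CCN", "CCCCCC"))
  ids <- vectorize_smiles("", v)
  expect_true(all(ids == 1))                              # all padding
  long <- paste(rep("C", 50), collapse = "")
  expect_equal(ncol(vectorize_smiles(long, v)), v$output_length)
  # unknown characters map to the reserved unknown id
  ids_u <- vectorize_smiles("CXC", v)
  expect_equal(ids_u[1, 2], 2L)
  # round trip on known characters
  expect_equal(devectorize_smiles(vectorize_smiles("CCO", v)[1, ], v), "CCO")
})

test_that("latent encoders are deterministic with the configured width", {
  enc <- latent_encoder_hash(width = 96)
  z <- latent_encode(c("CCO", "CCO", "c1ccccc1"), enc)
  expect_equal(ncol(z$matrix), 96)
  expect_equal(z$matrix[1, ], z$matrix[2, ])
  expect_false(all(z$matrix[1, ] == z$matrix[3, ]))
  expect_error(latent_encode("CCO", NULL), "encoder handle")
})

test_that("the trainable autoencoder compresses to the latent width", {
  b <- small_benchmark()
  enc <- latent_encoder_autoencoder(b$lib$canonical_smiles[1:60], width = 16,
                                    input_width = 128, epochs = 5, seed = 2)
  z <- predict(enc, c("CCO", "CCO"))
  expect_equal(dim(z), c(2L, 16L))
  expect_equal(z[1, ], z[2, ])                           # deterministic given weights
})

test_that("feature preprocessing enforces its thresholds and fit/apply split", {
  set.seed(3)
  X <- cbind(
    a = rnorm(60, sd = 2), b = rnorm(60),
    const = rep(1, 60),                      # variance 0 -> dropped
    c = rnorm(60)
  )
  X <- cbind(X, dup = X[, "a"])              # |r| = 1 -> one of the pair kept
  X[5, "b"] <- NA                            # imputed by training median
  tr <- aopqsar:::new_feature_bundle("descriptors", X, colnames(X),
                                     as.character(1:60))
  te_mat <- X[1:10, , drop = FALSE] + 5
  te <- aopqsar:::new_feature_bundle("descriptors", te_mat, colnames(X),
                                     as.character(1:10))
  out <- preprocess_features(tr, te)
  Xtr <- out[[1]]$matrix
  expect_false("const" %in% colnames(Xtr))
  expect_equal(sum(c("a", "dup") %in% colnames(Xtr)), 1)
  expect_true(all(abs(colMeans(Xtr)) < 1e-10))
  expect_equal(unname(apply(Xtr, 2, sd)), rep(1, ncol(Xtr)))
  # retained training features satisfy the thresholds
  kept_raw <- X[, colnames(Xtr), drop = FALSE]
  kept_raw[is.na(kept_raw)] <- 0
  expect_true(all(apply(kept_raw, 2, var) >= 0.1))
  cm <- cor(kept_raw)
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.9))
  # the held-out transform uses training statistics only: the shifted test
  # set keeps its offset instead of being re-centred
  expect_gt(min(colMeans(out[[2]]$matrix)), 1)
  expect_error(preprocess_features(
    aopqsar:::new_feature_bundle("descriptors", matrix(1, 10, 2),
                                 c("x", "y"), as.character(1:10))),
    "variance filter")
})
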