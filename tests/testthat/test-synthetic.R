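test_that("libraries honor exact class counts with a real structural signal", {
  b <- small_benchmark()
  lib <- b$lib
  expect_equal(nrow(lib), 200)
  expect_equal(sum(lib$toxicophore_present), 60)
  expect_equal(dplyr::n_distinct(lib$canonical_smiles), 200)
  # noise-free: substructure search exactly predicts activity
  expect_equal(has_toxicophore(lib$canonical_smiles), lib$toxicophore_present)
  expect_equal(lib$active, lib$toxicophore_present)
  # curation stability: the generated structures are already canonical parents
  expect_equal(canonicalize_smiles(lib$canonical_smiles, strip_stereo = TRUE),
               lib$canonical_smiles)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- synthetic_config(20, 30, seed = 7L)
  l1 <- generate_library(cfg)
  l2 <- generate_library(cfg)
  expect_identical(l1, l2)
  cfg2 <- synthetic_config(20, 30, seed = 8L)
  l3 <- generate_library(cfg2)
  overlap <- mean(l1$canonical_smiles %in% l3$canonical_smiles)
  expect_lt(overlap, 0.5)
})

test_that("label noise flips the stated fraction of labels", {
  cfg <- synthetic_config(40, 60, label_noise = 0.2, seed = 3L)
  lib <- generate_library(cfg)
  expect_equal(sum(lib$active != lib$toxicophore_present), 20)
})

test_that("assay matrices recover truth in the noiseless limit and drop all-missing", {
  cfg0 <- synthetic_config(25, 75, assay_specs = default_assay_specs(4, 1, 0, 0),
                           seed = 9L)
  lib0 <- generate_library(cfg0)
  am <- generate_assay_matrix(lib0, cfg0)
  ds <- aggregate_hitcalls(am, paste0("assay_", 1:4))
  expect_equal(ds$active, lib0$active)
  # all-missing: every compound excluded
  cfg1 <- synthetic_config(25, 75, assay_specs = default_assay_specs(2, 1, 0, 1),
                           seed = 9L)
  am1 <- generate_assay_matrix(lib0, cfg1)
  ds1 <- aggregate_hitcalls(am1, paste0("assay_", 1:2))
  expect_equal(nrow(ds1), 0)
  expect_equal(nrow(attr(ds1, "excluded")), 100)
})

test_that("uninformative assays carry no learnable signal", {
  cfg <- synthetic_config(200, 300, assay_specs = default_assay_specs(3, 0.3, 0.3, 0),
                          seed = 13L)
  lib <- generate_library(cfg)
  am <- generate_assay_matrix(lib, cfg)
  ds <- aggregate_hitcalls(am, paste0("assay_", 1:3))
  # labels are now independent of structure: a fingerprint model cannot beat
  # chance by a margin
  fp <- compute_circular_fp(ds$compound)
  fit_fun <- function(X, y) {
    m <- build_model(model_spec("logreg", "circular_fp", seed = 1))
    train_model(m, list(X = X, y = y))
  }
  cv <- repeated_kfold_cv(fp$matrix, ds$active, fit_fun, k = 5, iterations = 1,
                          seed = 2)
  ba <- attr(cv, "summary")
  ba <- ba$mean[ba$metric == "balanced_accuracy"]
  expect_lt(abs(ba - 0.5), 0.1)
})

test_that("presets reproduce the endpoint sizes and imbalances", {
  # the small presets in full; the large one is exercised in the acceptance
  # suite
  b1 <- generate_benchmark("mie1_like", seed = 21)
  expect_equal(b1$summary$n, 232)
  expect_equal(b1$summary$pct_active, 79)
  b2 <- generate_benchmark("ke1_like", seed = 22)
  expect_equal(b2$summary$n, 636)
  expect_equal(b2$summary$pct_active, 30)
  expect_equal(attr(b2$dataset, "endpoint"), "KE1")
  # writes the CSV dialects the readers consume
  d <- tempfile(); b3 <- generate_benchmark("mie1_like", seed = 21, dir = d)
  expect_true(all(file.exists(file.path(d, c("compounds.csv", "hitcalls.csv",
                                             "endpoint.yaml")))))
  calls <- read_hitcalls(file.path(d, "hitcalls.csv"))
  expect_equal(nrow(calls), 232)
})
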