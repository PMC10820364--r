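# Shared fixtures, built once per test run. Sizes are kept small; the
# synthetic grammar guarantees the planted nitroaromatic signal.

fixture_env <- new.env()

small_benchmark <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- aopqsar::synthetic_config(60, 140, seed = 101L)
    lib <- aopqsar::generate_library(cfg)
    ds <- tibble::tibble(compound = lib$canonical_smiles, active = lib$active)
    fixture_env$small <- list(cfg = cfg, lib = lib, dataset = ds)
  }
  fixture_env$small
}

small_split_fp <- function() {
  if (is.null(fixture_env$split_fp)) {
    b <- small_benchmark()
    sp <- aopqsar::stratified_split(b$dataset, 0.2, seed = 5L)
    fixture_env$split_fp <- list(
      split = sp,
      fp_train = aopqsar::compute_circular_fp(sp$train),
      fp_test = aopqsar::compute_circular_fp(sp$test)
    )
  }
  fixture_env$split_fp
}

# independent linear "model" used by explainability tests: predict() is a
# plain affine function of the features
new_test_linear <- function(w, b = 0) {
  structure(list(w = w, b = b), class = "test_linear")
}
predict.test_linear <- function(object, newdata, ...) {
  as.vector(as.matrix(newdata) %*% object$w + object$b)
}
registerS3method("predict", "test_linear", predict.test_linear,
                 envir = asNamespace("stats"))
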