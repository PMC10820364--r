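test_that("every baseline family trains and emits calibrated-range probabilities", {
  b <- small_split_fp()
  X <- b$fp_train$matrix; y <- b$split$train$active
  Xt <- b$fp_test$matrix
  for (fam in c("logreg", "dtree", "rforest", "balanced_rforest",
                "grad_boost", "svm", "knn", "gnb")) {
    m <- build_model(model_spec(fam, "circular_fp", seed = 3))
    m <- train_model(m, list(X = X, y = y))
    p <- predict(m, Xt)
    expect_length(p, nrow(Xt))
    expect_true(all(p >= 0 & p <= 1), info = fam)
    expect_type(predict(m, Xt, type = "label"), "logical")
  }
})

test_that("the noise-free signal is recovered by fingerprint baselines", {
  b <- small_split_fp()
  m <- build_model(model_spec("rforest", "circular_fp", seed = 2))
  m <- train_model(m, list(X = b$fp_train$matrix, y = b$split$train$active))
  met <- compute_metrics(b$split$test$active,
                         predict(m, b$fp_test$matrix) >= 0.5)
  expect_gte(met$balanced_accuracy, 0.95)
})

test_that("sequence model learns from tokenized SMILES", {
  b <- small_benchmark()
  sp <- stratified_split(b$dataset, 0.2, seed = 6)
  vocab <- build_vocabulary(sp$train$compound)
  tok_tr <- vectorize_smiles(sp$train$compound, vocab)
  tok_te <- vectorize_smiles(sp$test$compound, vocab)
  spec <- model_spec("nlp_seq", seed = 5,
                     hyperparameters = list(embedding_dim = 16,
                                            lstm_units = 32, gru_units = 16))
  m <- build_model(spec, vocab_size = length(vocab$characters))
  m <- train_model(m, list(tokens = tok_tr, y = sp$train$active),
                   train_config(max_epochs = 20))
  met <- compute_metrics(sp$test$active, predict(m, tok_te) >= 0.5)
  expect_gte(met$balanced_accuracy, 0.8)
  expect_s3_class(m$history, "tbl_df")
  expect_true(all(c("epoch", "train_loss", "val_loss", "lr") %in% names(m$history)))
})

test_that("the learning rate decays by the configured factor on a plateau", {
  set.seed(3)
  # pure-noise problem: validation loss plateaus quickly
  X <- matrix(rnorm(80 * 4), 80)
  y <- rbinom(80, 1, 0.5)
  spec <- model_spec("dnn", "latent",
                     hyperparameters = list(hidden = c(8), dropout = 0), seed = 1)
  m <- build_model(spec, input_dim = 4)
  m <- train_model(m, list(X = X, y = y),
                   train_config(max_epochs = 60, plateau_patience = 3,
                                lr_decay_factor = 10))
  lrs <- unique(m$history$lr)
  expect_true(length(lrs) >= 2)                 # at least one decay happened
  expect_equal(lrs[1] / lrs[2], 10)
  expect_lt(nrow(m$history), 60)               # stopped at the second plateau
})

test_that("multimodal model consumes all five representations", {
  b <- small_benchmark()
  sp <- stratified_split(b$dataset, 0.2, seed = 8)
  spec <- model_spec("multimodal", seed = 7, hyperparameters = list(
    branch_hidden = list(maccs_fp = c(32, 16), circular_fp = c(64, 32),
                         descriptors = c(32, 16), latent = c(32, 16),
                         tokens = c(32, 16)),
    embedding_dim = 8, head = c(32, 16)))
  prep <- prepare_model_data(spec, sp$train)
  prep_te <- prepare_model_data(spec, sp$test, state = prep$state)
  dims <- lapply(prep$data[c("maccs_fp", "circular_fp", "descriptors", "latent")],
                 ncol)
  m <- build_model(spec, vocab_size = length(prep$state$vocab$characters),
                   branch_input_dims = dims)
  m <- train_model(m, prep$data, train_config(max_epochs = 12))
  p <- predict(m, prep_te$data)
  expect_length(p, nrow(sp$test))
  met <- compute_metrics(sp$test$active, p >= 0.5)
  expect_gte(met$balanced_accuracy, 0.8)
})

test_that("glance and autoplot summarise fitted models", {
  b <- small_split_fp()
  m <- build_model(model_spec("dnn", "circular_fp",
                              hyperparameters = list(hidden = c(16)), seed = 1),
                   input_dim = ncol(b$fp_train$matrix))
  m <- train_model(m, list(X = b$fp_train$matrix, y = b$split$train$active),
                   train_config(max_epochs = 4))
  g <- glance(m)
  expect_equal(g$family, "dnn")
  expect_equal(g$epochs, 4)
  expect_s3_class(autoplot(m), "ggplot")
})
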