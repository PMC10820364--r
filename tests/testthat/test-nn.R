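# Gradient correctness of the network engine against finite differences,
# plus the training-protocol contracts (bias init, reproducibility,
# thresholding).

num_grad_param <- function(net, X, y, layer, pname, eps = 1e-5,
                           forward = aopqsar:::nn_forward,
                           loss = aopqsar:::nn_loss_grad) {
  orig <- layer[[pname]]
  g <- orig * 0
  for (i in seq_along(orig)) {
    p1 <- orig; p1[i] <- p1[i] + eps
    layer[[pname]] <- p1
    l1 <- loss(net, forward(net, X), y)$loss
    p2 <- orig; p2[i] <- p2[i] - eps
    layer[[pname]] <- p2
    l2 <- loss(net, forward(net, X), y)$loss
    g[i] <- (l1 - l2) / (2 * eps)
  }
  layer[[pname]] <- orig
  g
}

test_that("dense, recurrent and embedding gradients match finite differences", {
  set.seed(2)
  nf <- aopqsar:::nn_forward; nl <- aopqsar:::nn_loss_grad
  nb <- aopqsar:::nn_backward
  # dense MLP
  X <- matrix(rnorm(15 * 4), 15); y <- matrix(rbinom(15, 1, 0.4), ncol = 1)
  net <- aopqsar:::nn_sequential(list(aopqsar:::nn_dense(4, 6, "relu"),
                                      aopqsar:::nn_dense(6, 1, "linear")),
                                 loss = "bce", seed = 3)
  nb(net, nl(net, nf(net, X), y)$grad)
  for (spec in list(c(1, "W"), c(1, "b"), c(2, "W"))) {
    l <- net$layers[[as.integer(spec[1])]]
    ana <- l[[paste0("g", spec[2])]]
    num <- num_grad_param(net, X, y, l, spec[2])
    expect_lt(max(abs(ana - num)), 1e-6)
  }
  # embedding -> LSTM(sequences) -> GRU -> dense
  ids <- matrix(sample(1:7, 4 * 6, replace = TRUE), 4)
  ys <- matrix(c(1, 0, 1, 0), ncol = 1)
  net2 <- aopqsar:::nn_sequential(list(
    aopqsar:::nn_embedding(7, 4),
    aopqsar:::nn_lstm(4, 5, return_sequences = TRUE),
    aopqsar:::nn_gru(5, 3),
    aopqsar:::nn_dense(3, 1, "linear")), loss = "bce", seed = 4)
  nb(net2, nl(net2, nf(net2, ids), ys)$grad)
  checks <- list(c(1, "W"), c(2, "Wx"), c(2, "Wh"), c(2, "b"),
                 c(3, "Wx"), c(3, "Wh"), c(3, "b"))
  for (spec in checks) {
    l <- net2$layers[[as.integer(spec[1])]]
    ana <- l[[paste0("g", spec[2])]]
    num <- num_grad_param(net2, ids, ys, l, spec[2])
    expect_lt(max(abs(ana - num)), 1e-6)
  }
  # embedding -> mean pooling -> dense
  net3 <- aopqsar:::nn_sequential(list(
    aopqsar:::nn_embedding(7, 4), aopqsar:::nn_meanpool(),
    aopqsar:::nn_dense(4, 1, "linear")), loss = "bce", seed = 5)
  nb(net3, nl(net3, nf(net3, ids), ys)$grad)
  l <- net3$layers[[1]]
  expect_lt(max(abs(l$gW - num_grad_param(net3, ids, ys, l, "W"))), 1e-6)
})

test_that("message-passing gradients match finite differences", {
  graphs <- featurize_graph(c("CCO", "c1ccccc1", "O=[N+]([O-])c1ccc(Cl)cc1", "C"))
  y <- matrix(c(0, 1, 1, 0), ncol = 1)
  net <- aopqsar:::mpnn_new(hidden = 5, rounds = 2, head = c(4), seed = 2)
  bt <- aopqsar:::batch_graphs(graphs)
  fwd <- function(n, b) aopqsar:::mpnn_forward(n, b)
  lg <- aopqsar:::nn_loss_grad(net, fwd(net, bt), y)
  aopqsar:::mpnn_backward(net, lg$grad)
  for (p in aopqsar:::mpnn_param_names) {
    ana <- net$grads[[p]]
    orig <- net[[p]]
    g <- orig * 0
    for (i in seq_along(orig)) {
      p1 <- orig; p1[i] <- p1[i] + 1e-5; net[[p]] <- p1
      l1 <- aopqsar:::nn_loss_grad(net, fwd(net, bt), y)$loss
      p2 <- orig; p2[i] <- p2[i] - 1e-5; net[[p]] <- p2
      l2 <- aopqsar:::nn_loss_grad(net, fwd(net, bt), y)$loss
      g[i] <- (l1 - l2) / 2e-5
    }
    net[[p]] <- orig
    expect_lt(max(abs(ana - g)), 1e-6)
  }
})

test_that("output-bias initialization reproduces the class ratio", {
  set.seed(6)
  X <- matrix(rnorm(200 * 5), 200)
  y <- rep(c(1, 0), c(46, 154))                  # 23% positives
  spec <- model_spec("dnn", "maccs_fp",
                     hyperparameters = list(hidden = c(8), dropout = 0),
                     seed = 2)
  m <- build_model(spec, input_dim = 5)
  # zero training epochs: predictions reflect the initial bias only
  m <- train_model(m, list(X = X, y = y),
                   train_config(max_epochs = 0, validation_fraction = 0))
  p <- predict(m, X)
  expect_equal(mean(p), 0.23, tolerance = 1e-6)
})

test_that("a separable problem is fit perfectly by logistic regression", {
  set.seed(7)
  X <- rbind(matrix(rnorm(30 * 2, mean = -3), ncol = 2),
             matrix(rnorm(30 * 2, mean = 3), ncol = 2))
  y <- rep(c(FALSE, TRUE), each = 30)
  m <- build_model(model_spec("logreg", "latent", seed = 1))
  m <- train_model(m, list(X = X, y = y))
  met <- compute_metrics(y, predict(m, X) >= 0.5)
  expect_equal(met$balanced_accuracy, 1.0)
})

test_that("fits are reproducible, probabilistic and row-independent", {
  b <- small_split_fp()
  X <- b$fp_train$matrix; y <- b$split$train$active
  spec <- model_spec("dnn", "circular_fp",
                     hyperparameters = list(hidden = c(16, 8)), seed = 9)
  fit_once <- function() {
    m <- build_model(spec, input_dim = ncol(X))
    m <- train_model(m, list(X = X, y = y), train_config(max_epochs = 5))
    predict(m, b$fp_test$matrix)
  }
  p1 <- fit_once(); p2 <- fit_once()
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # permuting input rows permutes outputs identically
  m <- build_model(spec, input_dim = ncol(X))
  m <- train_model(m, list(X = X, y = y), train_config(max_epochs = 3))
  perm <- sample(nrow(b$fp_test$matrix))
  expect_equal(predict(m, b$fp_test$matrix[perm, ]), predict(m, b$fp_test$matrix)[perm])
  # >= rule at the 0.5 boundary
  lab <- predict(m, b$fp_test$matrix, type = "label")
  expect_equal(lab, predict(m, b$fp_test$matrix) >= 0.5)
})

test_that("architecture contracts are enforced", {
  expect_error(build_model(model_spec("dnn", "maccs_fp",
                                      hyperparameters = list(hidden = c(100))),
                           input_dim = 10),
               "powers of 2")
  spec_ok <- model_spec("dnn", "maccs_fp",
                        hyperparameters = list(hidden = c(256, 128, 64)))
  expect_s3_class(build_model(spec_ok, input_dim = 10), "qsar_model")
  # multimodal: exactly five branch submodules
  spec_mm <- model_spec("multimodal", seed = 1)
  m <- build_model(spec_mm, vocab_size = 20,
                   branch_input_dims = list(maccs_fp = 166, circular_fp = 64,
                                            descriptors = 30, latent = 32))
  expect_length(m$engine$branches, 5)
  # T = 0 message rounds is a legal degenerate baseline
  m0 <- build_model(model_spec("mpnn", hyperparameters = list(rounds = 0)))
  g <- featurize_graph(c("CCO", "CCC", "CCN", "CCCl", "CCO", "c1ccccc1"))
  m0 <- train_model(m0, list(graphs = g, y = c(1, 0, 1, 0, 1, 0)),
                    train_config(max_epochs = 2, validation_fraction = 0.3))
  expect_length(predict(m0, g), 6)
  # encoder/family incompatibilities
  expect_error(model_spec("nlp_seq", "descriptors"), "token")
  expect_error(model_spec("mpnn", "maccs_fp"), "graph")
  expect_error(model_spec("logreg", "graph"), "tabular")
})
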