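# The model battery: eight baseline ML families behind one fit/predict
# surface, a dense network, a character-sequence (LSTM/GRU) network, a
# message-passing graph network, and the five-branch multimodal fusion
# network, with the shared training protocol (mini-batches of 32, 10%
# validation split, output-bias initialization, plateau learning-rate decay).

MODEL_FAMILIES <- c("logreg", "dtree", "rforest", "balanced_rforest",
                    "grad_boost", "svm", "knn", "gnb",
                    "dnn", "nlp_seq", "mpnn", "multimodal")
TABULAR_ENCODERS <- c("descriptors", "circular_fp", "maccs_fp", "latent")
MULTIMODAL_ENCODERS <- c("maccs_fp", "circular_fp", "descriptors", "tokens", "latent")

#' Specify a model
#'
#' Validates family/encoder compatibility: graph input only with the
#' message-passing network, token sequences only with the sequence model (or
#' the multimodal token branch), tabular encoders with everything else.
#'
#' @param family One of the twelve supported families.
#' @param encoders Encoder name(s): a single tabular encoder for baselines
#'   and the dense network, `"tokens"` for `nlp_seq`, `"graph"` for `mpnn`,
#'   the five fusion encoders (default) for `multimodal`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed used for every stochastic element of the fit.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = MODEL_FAMILIES, encoders = NULL,
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  encoders <- encoders %||% switch(family,
    nlp_seq = "tokens", mpnn = "graph",
    multimodal = MULTIMODAL_ENCODERS, "descriptors")
  if (family == "nlp_seq" && !identical(encoders, "tokens")) {
    stop("model_spec: nlp_seq takes the token-sequence encoder only")
  }
  if (family == "mpnn" && !identical(encoders, "graph")) {
    stop("model_spec: mpnn takes the graph encoder only")
  }
  if (family == "multimodal") {
    if (!all(encoders %in% MULTIMODAL_ENCODERS) || length(encoders) != 5) {
      stop("model_spec: multimodal expects the five fusion encoders (",
           paste(MULTIMODAL_ENCODERS, collapse = ", "), ")")
    }
  }
  if (family %in% c("logreg", "dtree", "rforest", "balanced_rforest",
                    "grad_boost", "svm", "knn", "gnb", "dnn")) {
    if (length(encoders) != 1 || !encoders %in% TABULAR_ENCODERS) {
      stop("model_spec: family '", family, "' takes exactly one tabular ",
           "encoder (", paste(TABULAR_ENCODERS, collapse = ", "), ")")
    }
  }
  structure(list(family = family, encoders = encoders,
                 hyperparameters = hyperparameters, seed = as.integer(seed)),
            class = "model_spec")
}

#' Training configuration for the network families
#'
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Epoch cap (default 100).
#' @param validation_fraction Training share used as the validation set for
#'   plateau monitoring (default 0.10).
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate is decayed (default 10).
#' @param lr_decay_factor Decay divisor at a plateau (default 10); training
#'   stops at the second plateau.
#' @param lr Initial learning rate (default 1e-3, Adam).
#' @param init_output_bias_from_class_ratio Start the output bias at
#'   `log(p/(1-p))` of the training class ratio (default TRUE).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32, max_epochs = 100,
                         validation_fraction = 0.10, plateau_patience = 10,
                         lr_decay_factor = 10, lr = 1e-3,
                         init_output_bias_from_class_ratio = TRUE) {
  stopifnot(validation_fraction >= 0, validation_fraction < 0.5,
            lr_decay_factor > 1)
  structure(list(batch_size = batch_size, max_epochs = max_epochs,
                 validation_fraction = validation_fraction,
                 plateau_patience = plateau_patience,
                 lr_decay_factor = lr_decay_factor, lr = lr,
                 init_output_bias = init_output_bias_from_class_ratio),
            class = "train_config")
}

default_hp <- function(family) {
  switch(family,
    logreg = list(lambda = 1e-3),
    dtree = list(minsplit = 20, cp = 0.01),
    rforest = list(num_trees = 300, mtry = NULL),
    balanced_rforest = list(num_trees = 300, mtry = NULL),
    grad_boost = list(nrounds = 150, max_depth = 4, eta = 0.1),
    svm = list(cost = 1, kernel = "radial"),
    knn = list(k = 5),
    gnb = list(laplace = 0),
    dnn = list(hidden = c(512, 256, 128), dropout = 0.2),
    nlp_seq = list(embedding_dim = 64, lstm_units = 128, gru_units = 64),
    mpnn = list(hidden = 64, rounds = 3, head = c(64)),
    multimodal = list(
      branch_hidden = list(maccs_fp = c(256, 128), circular_fp = c(512, 256, 128),
                           descriptors = c(256, 128), latent = c(128, 64),
                           tokens = c(128, 64)),
      embedding_dim = 64, dropout = 0.2, head = c(256, 64)
    ),
    list()
  )
}

spec_hp <- function(spec) {
  utils::modifyList(default_hp(spec$family), spec$hyperparameters)
}

is_power_of_two <- function(x) x > 0 & bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L

#' Build an untrained model from a specification
#'
#' Network families are instantiated with their architecture (dense stacks
#' with dropout and power-of-two widths; embedding + LSTM + GRU for the
#' sequence model; message passing with gated updates for the graph model;
#' five dense/recurrent branches merged by concatenation for the multimodal
#' model). Baseline families defer to their backing learners at fit time.
#'
#' @param spec A [model_spec()].
#' @param input_dim Input feature count (tabular networks).
#' @param vocab_size,seq_length Vocabulary and padded length (token models).
#' @param branch_input_dims Named widths of the tabular fusion branches
#'   (multimodal).
#' @return An untrained `qsar_model`.
#' @export
build_model <- function(spec, input_dim = NULL, vocab_size = NULL,
                        seq_length = NULL, branch_input_dims = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  hp <- spec_hp(spec)
  engine <- NULL
  if (spec$family == "dnn") {
    stopifnot(!is.null(input_dim))
    if (!all(is_power_of_two(hp$hidden))) {
      stop("build_model: dnn hidden widths must be powers of 2, got ",
           paste(hp$hidden, collapse = ", "))
    }
    dims <- c(input_dim, hp$hidden)
    layers <- lapply(seq_len(length(dims) - 1), function(i) {
      nn_dense(dims[i], dims[i + 1], activation = "relu", dropout = hp$dropout)
    })
    layers <- c(layers, list(nn_dense(dims[length(dims)], 1, activation = "linear")))
    engine <- nn_sequential(layers, loss = "bce", seed = spec$seed)
  } else if (spec$family == "nlp_seq") {
    stopifnot(!is.null(vocab_size))
    engine <- nn_sequential(list(
      nn_embedding(vocab_size, hp$embedding_dim),
      nn_lstm(hp$embedding_dim, hp$lstm_units, return_sequences = TRUE),
      nn_gru(hp$lstm_units, hp$gru_units, return_sequences = FALSE),
      nn_dense(hp$gru_units, 1, activation = "linear")
    ), loss = "bce", seed = spec$seed)
  } else if (spec$family == "mpnn") {
    engine <- mpnn_new(hidden = hp$hidden, rounds = hp$rounds, head = hp$head,
                       seed = spec$seed)
  } else if (spec$family == "multimodal") {
    stopifnot(!is.null(branch_input_dims), !is.null(vocab_size))
    engine <- multimodal_new(hp, branch_input_dims, vocab_size, seed = spec$seed)
  }
  structure(list(spec = spec, hp = hp, engine = engine, fit = NULL,
                 trained = FALSE, history = NULL),
            class = c(paste0("qsar_", spec$family), "qsar_model"))
}

#' @exportS3Method base::print
print.qsar_model <- function(x, ...) {
  cat("<qsar_model>", x$spec$family, "on",
      paste(x$spec$encoders, collapse = "+"),
      if (x$trained) "(trained)" else "(untrained)", "\n")
  invisible(x)
}

#' Train a model
#'
#' Baseline families fit their backing learner on the (optionally
#' pre-oversampled) feature matrix. Network families split off the
#' validation fraction, optionally initialize the output bias from the class
#' ratio, decay the learning rate on a validation-loss plateau and stop on
#' the second plateau; the per-epoch history is stored on the result.
#'
#' @param model An untrained model from [build_model()].
#' @param data Named list: `X` (feature matrix) for tabular families,
#'   `tokens` for the sequence model, `graphs` for the graph model, the five
#'   encoder matrices (`maccs_fp`, `circular_fp`, `descriptors`, `latent`,
#'   `tokens`) for multimodal; always `y` (binary labels).
#' @param config A [train_config()] (network families).
#' @return The trained `qsar_model`.
#' @export
train_model <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "qsar_model"))
  spec <- model$spec
  hp <- model$hp
  y <- as.logical(data$y)
  fam <- spec$family
  if (fam %in% c("logreg", "dtree", "rforest", "balanced_rforest",
                 "grad_boost", "svm", "knn", "gnb")) {
    X <- as.matrix(data$X)
    stopifnot(nrow(X) == length(y))
    model$fit <- fit_baseline(fam, X, y, hp, spec$seed)
  } else if (fam == "dnn") {
    model$history <- nn_fit(model$engine, as.matrix(data$X), as.numeric(y),
                            epochs = config$max_epochs,
                            batch_size = config$batch_size,
                            validation_fraction = config$validation_fraction,
                            lr = config$lr,
                            plateau_patience = config$plateau_patience,
                            lr_decay_factor = config$lr_decay_factor,
                            init_output_bias = config$init_output_bias,
                            seed = spec$seed)
  } else if (fam == "nlp_seq") {
    model$history <- nn_fit(model$engine, data$tokens, as.numeric(y),
                            epochs = config$max_epochs,
                            batch_size = config$batch_size,
                            validation_fraction = config$validation_fraction,
                            lr = config$lr,
                            plateau_patience = config$plateau_patience,
                            lr_decay_factor = config$lr_decay_factor,
                            init_output_bias = config$init_output_bias,
                            seed = spec$seed)
  } else if (fam == "mpnn") {
    model$history <- mpnn_fit(model$engine, data$graphs, y,
                              epochs = config$max_epochs,
                              batch_size = config$batch_size,
                              validation_fraction = config$validation_fraction,
                              lr = config$lr,
                              plateau_patience = config$plateau_patience,
                              lr_decay_factor = config$lr_decay_factor,
                              init_output_bias = config$init_output_bias,
                              seed = spec$seed)
  } else if (fam == "multimodal") {
    model$history <- multimodal_fit(model$engine, data, y, config,
                                    seed = spec$seed)
  }
  model$trained <- TRUE
  model
}

fit_baseline <- function(family, X, y, hp, seed) {
  yf <- factor(ifelse(y, "active", "inactive"), levels = c("inactive", "active"))
  withr::with_seed(seed, switch(family,
    logreg = {
      fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = 0,
                            lambda = hp$lambda, standardize = FALSE)
      list(kind = "logreg", fit = fit)
    },
    dtree = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- yf
      list(kind = "dtree",
           fit = rpart::rpart(.y ~ ., data = df,
                              control = rpart::rpart.control(
                                minsplit = hp$minsplit, cp = hp$cp)))
    },
    rforest = {
      list(kind = "ranger",
           fit = ranger::ranger(x = X, y = yf, probability = TRUE,
                                num.trees = hp$num_trees,
                                mtry = hp$mtry %||% floor(sqrt(ncol(X))),
                                seed = seed, num.threads = 1))
    },
    balanced_rforest = {
      frac <- min(table(yf)) / length(yf)   # balanced per-class bootstraps
      list(kind = "ranger",
           fit = ranger::ranger(x = X, y = yf, probability = TRUE,
                                num.trees = hp$num_trees,
                                mtry = hp$mtry %||% floor(sqrt(ncol(X))),
                                sample.fraction = c(frac, frac), replace = TRUE,
                                seed = seed, num.threads = 1))
    },
    grad_boost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      list(kind = "xgb", fit = fit)
    },
    svm = {
      list(kind = "svm",
           fit = suppressWarnings(
             e1071::svm(X, yf, kernel = hp$kernel, cost = hp$cost,
                        probability = TRUE)))
    },
    knn = {
      list(kind = "knn", X = X, y = yf, k = hp$k)
    },
    gnb = {
      list(kind = "gnb",
           fit = e1071::naiveBayes(X, yf, laplace = hp$laplace))
    }
  ))
}

#' Predict activity probabilities (and labels at 0.5)
#'
#' @param object A trained `qsar_model`.
#' @param newdata Input matching the model's encoder: feature matrix, token
#'   matrix, graph list, or the multimodal named list.
#' @param type `"prob"` (default) or `"label"` (probability >= 0.5).
#' @param ... Unused.
#' @return Numeric probabilities in `[0, 1]`, or logical labels.
#' @export
predict.qsar_model <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  stopifnot(object$trained)
  fam <- object$spec$family
  p <- if (fam %in% c("logreg", "dtree", "rforest", "balanced_rforest",
                      "grad_boost", "svm", "knn", "gnb")) {
    predict_baseline(object$fit, as.matrix(newdata))
  } else if (fam == "dnn") {
    nn_predict_prob(object$engine, as.matrix(newdata))
  } else if (fam == "nlp_seq") {
    nn_predict_prob(object$engine, newdata)
  } else if (fam == "mpnn") {
    mpnn_predict_prob(object$engine, newdata)
  } else if (fam == "multimodal") {
    multimodal_predict_prob(object$engine, newdata)
  }
  if (type == "label") p >= 0.5 else p
}

predict_baseline <- function(fit, X) {
  switch(fit$kind,
    logreg = as.vector(stats::predict(fit$fit, X, type = "response")),
    dtree = {
      pr <- stats::predict(fit$fit, data.frame(X, check.names = FALSE), type = "prob")
      as.vector(pr[, "active"])
    },
    ranger = {
      pr <- stats::predict(fit$fit, data = X, num.threads = 1)$predictions
      as.vector(pr[, "active"])
    },
    xgb = as.vector(stats::predict(fit$fit, xgboost::xgb.DMatrix(X))),
    svm = {
      pr <- attr(stats::predict(fit$fit, X, probability = TRUE), "probabilities")
      as.vector(pr[, "active"])
    },
    knn = {
      pred <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "active", win, 1 - win)
    },
    gnb = {
      pr <- stats::predict(fit$fit, X, type = "raw")
      as.vector(pr[, "active"])
    }
  )
}

# ---- multimodal fusion network ----------------------------------------------

multimodal_new <- function(hp, branch_input_dims, vocab_size, seed = 1L) {
  net <- new.env(parent = emptyenv())
  net$order <- MULTIMODAL_ENCODERS
  net$branches <- list()
  k <- 0L
  for (enc in net$order) {
    k <- k + 1L
    widths <- hp$branch_hidden[[enc]]
    if (enc == "tokens") {
      dims <- c(hp$embedding_dim, widths)
      layers <- list(nn_embedding(vocab_size, hp$embedding_dim), nn_meanpool())
    } else {
      dims <- c(branch_input_dims[[enc]], widths)
      layers <- list()
    }
    for (i in seq_len(length(dims) - 1)) {
      layers <- c(layers, list(nn_dense(dims[i], dims[i + 1],
                                        activation = "relu",
                                        dropout = hp$dropout)))
    }
    net$branches[[enc]] <- nn_sequential(layers, loss = "bce", seed = seed + k)
  }
  concat_dim <- sum(vapply(net$order, function(enc) {
    utils::tail(hp$branch_hidden[[enc]], 1)
  }, numeric(1)))
  head_dims <- c(concat_dim, hp$head)
  head_layers <- lapply(seq_len(length(head_dims) - 1), function(i) {
    nn_dense(head_dims[i], head_dims[i + 1], activation = "relu",
             dropout = hp$dropout)
  })
  head_layers <- c(head_layers,
                   list(nn_dense(head_dims[length(head_dims)], 1,
                                 activation = "linear")))
  net$head <- nn_sequential(head_layers, loss = "bce", seed = seed)
  net$loss <- "bce"
  net$seed <- as.integer(seed)
  class(net) <- "multimodal_net"
  net
}

multimodal_forward <- function(net, data, training = FALSE) {
  outs <- lapply(net$order, function(enc) {
    nn_forward(net$branches[[enc]], data[[enc]], training = training)
  })
  widths <- vapply(outs, ncol, integer(1))
  Z <- nn_forward(net$head, do.call(cbind, outs), training = training)
  list(Z = Z, widths = widths)
}

multimodal_backward <- function(net, dZ, widths) {
  dC <- nn_backward(net$head, dZ)
  off <- 0L
  for (i in seq_along(net$order)) {
    enc <- net$order[i]
    dBranch <- dC[, (off + 1):(off + widths[i]), drop = FALSE]
    nn_backward(net$branches[[enc]], dBranch)
    off <- off + widths[i]
  }
  invisible(NULL)
}

multimodal_take <- function(data, order, idx) {
  out <- lapply(order, function(enc) {
    x <- data[[enc]]
    if (is.array(x) && length(dim(x)) == 3) x[idx, , , drop = FALSE]
    else x[idx, , drop = FALSE]
  })
  names(out) <- order
  out
}

multimodal_fit <- function(net, data, y, config = train_config(), seed = 1L) {
  stopifnot(all(net$order %in% names(data)))
  y <- as.numeric(y)
  n <- length(y)
  withr::with_seed(seed, {
    if (config$init_output_bias) {
      p1 <- min(max(mean(y), 1e-6), 1 - 1e-6)
      out_layer <- net$head$layers[[length(net$head$layers)]]
      out_layer$b <- rep(log(p1 / (1 - p1)), 1)
      out_layer$W[] <- 0
    }
    val_idx <- if (config$validation_fraction > 0) {
      stratified_indices(y, config$validation_fraction)
    } else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    for (b in net$branches) adam_init(b)
    adam_init(net$head)
    data_tr <- multimodal_take(data, net$order, tr_idx)
    data_va <- if (length(val_idx)) multimodal_take(data, net$order, val_idx)
    lr <- config$lr
    best <- Inf; since_best <- 0L; plateaus <- 0L
    hist <- list()
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(length(tr_idx))
      tot <- 0; nb <- 0
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, length(ord))]
        batch <- multimodal_take(data_tr, net$order, bi)
        fw <- multimodal_forward(net, batch, training = TRUE)
        lg <- nn_loss_grad(net, fw$Z, matrix(y[tr_idx][bi], ncol = 1))
        if (!is.finite(lg$loss)) stop("multimodal_fit: non-finite loss")
        multimodal_backward(net, lg$grad, fw$widths)
        adam_step(net$head, lr)
        for (b in net$branches) adam_step(b, lr)
        tot <- tot + lg$loss; nb <- nb + 1
      }
      val_loss <- if (length(val_idx)) {
        fwv <- multimodal_forward(net, data_va, training = FALSE)
        nn_loss_grad(net, fwv$Z, matrix(y[val_idx], ncol = 1))$loss
      } else tot / nb
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tot / nb,
                                   val_loss = val_loss, lr = lr)
      if (val_loss < best - 1e-6) {
        best <- val_loss; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$plateau_patience) {
          plateaus <- plateaus + 1L; since_best <- 0L
          if (plateaus >= 2L) break
          lr <- lr / config$lr_decay_factor
        }
      }
    }
    dplyr::bind_rows(hist)
  })
}

multimodal_predict_prob <- function(net, data) {
  fw <- multimodal_forward(net, data, training = FALSE)
  as.vector(sigmoid(fw$Z))
}

# ---- encoding helper ---------------------------------------------------------

#' Prepare model inputs from a compound table
#'
#' Computes the encoder representation(s) a specification needs from a
#' tibble of compounds (with `compound`/`canonical_smiles` and `active`
#' columns), reusing fitted state (vocabulary, latent encoder, descriptor
#' preprocessing) so train and test partitions stay consistent.
#'
#' @param spec A [model_spec()].
#' @param data Compound tibble.
#' @param state Optional list from a previous call (its `vocab`,
#'   `latent_encoder`, `preprocess` entries are reused); pass the state
#'   returned for the training partition when encoding held-out data.
#' @return List with the model `data` (ready for [train_model()]) and the
#'   fitted `state`.
#' @export
prepare_model_data <- function(spec, data, state = NULL) {
  smi <- compound_smiles(data)
  y <- if ("active" %in% names(data)) as.logical(data$active) else NULL
  state <- state %||% list()
  need <- spec$encoders
  out <- list(y = y)
  fitting <- is.null(state$fitted)

  encode_tabular <- function(enc) {
    bundle <- switch(enc,
      descriptors = compute_descriptors(smi),
      circular_fp = compute_circular_fp(smi),
      maccs_fp = compute_maccs_fp(smi),
      latent = {
        if (is.null(state$latent_encoder)) {
          state$latent_encoder <<- latent_encoder_hash()
        }
        latent_encode(smi, state$latent_encoder)
      })
    if (enc %in% c("descriptors", "latent")) {
      if (fitting) {
        pp <- preprocess_features(bundle)
        state$preprocess[[enc]] <<- pp$fitted_preprocess
        pp$matrix
      } else {
        apply_preprocess(bundle, state$preprocess[[enc]])$matrix
      }
    } else {
      bundle$matrix
    }
  }

  for (enc in need) {
    if (enc == "tokens") {
      if (is.null(state$vocab)) state$vocab <- build_vocabulary(smi)
      out$tokens <- vectorize_smiles(smi, state$vocab)
    } else if (enc == "graph") {
      out$graphs <- featurize_graph(smi)
    } else {
      out[[if (length(need) == 1) "X" else enc]] <- encode_tabular(enc)
    }
  }
  state$fitted <- TRUE
  list(data = out, state = state)
}
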