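# Minimal neural-network engine: dense / dropout / embedding / recurrent
# (LSTM, GRU) / sequence-pooling layers with manual backpropagation and Adam.
# Written for the moderate problem sizes of QSAR endpoint modelling; all
# gradients are validated against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors ------------------------------------------------------

nn_dense <- function(n_in, n_out, activation = c("relu", "linear", "tanh", "sigmoid"),
                     dropout = 0, name = NULL) {
  activation <- match.arg(activation)
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$name <- name
  e$n_in <- n_in; e$n_out <- n_out
  e$activation <- activation; e$dropout <- dropout
  e
}

nn_embedding <- function(vocab_size, dim, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "embedding"; e$name <- name
  e$vocab_size <- vocab_size; e$dim <- dim
  e
}

nn_lstm <- function(n_in, units, return_sequences = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "lstm"; e$name <- name
  e$n_in <- n_in; e$units <- units; e$return_sequences <- return_sequences
  e
}

nn_gru <- function(n_in, units, return_sequences = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "gru"; e$name <- name
  e$n_in <- n_in; e$units <- units; e$return_sequences <- return_sequences
  e
}

nn_meanpool <- function(name = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "meanpool"; e$name <- name
  e
}

# ---- parameter init ----------------------------------------------------------

glorot <- function(n_in, n_out) {
  matrix(stats::runif(n_in * n_out, -1, 1) * sqrt(6 / (n_in + n_out)), n_in, n_out)
}

init_layer <- function(l) {
  if (l$type == "dense") {
    l$W <- glorot(l$n_in, l$n_out); l$b <- rep(0, l$n_out)
  } else if (l$type == "embedding") {
    l$W <- matrix(stats::runif(l$vocab_size * l$dim, -0.05, 0.05), l$vocab_size, l$dim)
  } else if (l$type == "lstm") {
    l$Wx <- glorot(l$n_in, 4 * l$units); l$Wh <- glorot(l$units, 4 * l$units)
    l$b <- rep(0, 4 * l$units)
    l$b[(l$units + 1):(2 * l$units)] <- 1  # forget-gate bias
  } else if (l$type == "gru") {
    l$Wx <- glorot(l$n_in, 3 * l$units); l$Wh <- glorot(l$units, 3 * l$units)
    l$b <- rep(0, 3 * l$units)
  }
  invisible(l)
}

layer_param_names <- function(l) {
  switch(l$type,
    dense = c("W", "b"), embedding = "W",
    lstm = c("Wx", "Wh", "b"), gru = c("Wx", "Wh", "b"),
    character(0)
  )
}

# ---- model -------------------------------------------------------------------

nn_sequential <- function(layers, loss = c("bce", "mse"), seed = 1L) {
  loss <- match.arg(loss)
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$loss <- loss
  net$seed <- as.integer(seed)
  withr::with_seed(net$seed, for (l in layers) init_layer(l))
  net$adam <- NULL
  class(net) <- "nn_net"
  net
}

#' @exportS3Method base::print
print.nn_net <- function(x, ...) {
  cat("<nn_net>", length(x$layers), "layers, loss =", x$loss, "\n")
  for (l in x$layers) {
    cat("  -", l$type,
        switch(l$type,
          dense = paste0(l$n_in, "->", l$n_out, " (", l$activation,
                         if (l$dropout > 0) paste0(", dropout ", l$dropout) else "", ")"),
          embedding = paste0(l$vocab_size, "->", l$dim),
          lstm = paste0(l$n_in, "->", l$units,
                        if (l$return_sequences) " (sequences)" else ""),
          gru = paste0(l$n_in, "->", l$units,
                       if (l$return_sequences) " (sequences)" else ""),
          ""),
        "\n")
  }
  invisible(x)
}

apply_activation <- function(z, act) {
  switch(act, relu = pmax(z, 0), linear = z, tanh = tanh(z), sigmoid = sigmoid(z))
}

activation_grad <- function(a, z, act) {
  switch(act,
    relu = (z > 0) * 1, linear = matrix(1, nrow(z), ncol(z)),
    tanh = 1 - a^2, sigmoid = a * (1 - a))
}

# forward one layer; input X is a matrix (B x d) or array (B x T x d) /
# integer matrix of token ids for embedding
layer_forward <- function(l, X, training = FALSE) {
  if (l$type == "dense") {
    Z <- sweep(X %*% l$W, 2, l$b, "+")
    A <- apply_activation(Z, l$activation)
    cache <- list(X = X, Z = Z, A = A)
    if (training && l$dropout > 0) {
      mask <- matrix(stats::runif(length(A)) > l$dropout, nrow(A), ncol(A)) /
        (1 - l$dropout)
      A <- A * mask
      cache$mask <- mask
    }
    l$cache <- cache
    A
  } else if (l$type == "embedding") {
    B <- nrow(X); Tn <- ncol(X)
    out <- array(0, c(B, Tn, l$dim))
    for (t in seq_len(Tn)) out[, t, ] <- l$W[X[, t], , drop = FALSE]
    l$cache <- list(ids = X)
    out
  } else if (l$type == "meanpool") {
    l$cache <- list(Tn = dim(X)[2])
    apply(X, c(1, 3), mean)
  } else if (l$type == "lstm") {
    lstm_forward(l, X)
  } else if (l$type == "gru") {
    gru_forward(l, X)
  } else stop("unknown layer type ", l$type)
}

layer_backward <- function(l, dOut) {
  if (l$type == "dense") {
    cache <- l$cache
    dA <- dOut
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dZ <- dA * activation_grad(cache$A, cache$Z, l$activation)
    l$gW <- crossprod(cache$X, dZ)
    l$gb <- colSums(dZ)
    dZ %*% t(l$W)
  } else if (l$type == "embedding") {
    ids <- l$cache$ids
    gW <- matrix(0, l$vocab_size, l$dim)
    for (t in seq_len(ncol(ids))) {
      add <- rowsum(matrix(dOut[, t, ], nrow(ids)), group = ids[, t])
      gW[as.integer(rownames(add)), ] <- gW[as.integer(rownames(add)), ] + add
    }
    l$gW <- gW
    NULL  # no gradient past the ids
  } else if (l$type == "meanpool") {
    Tn <- l$cache$Tn
    B <- nrow(dOut); d <- ncol(dOut)
    out <- array(0, c(B, Tn, d))
    for (t in seq_len(Tn)) out[, t, ] <- dOut / Tn
    out
  } else if (l$type == "lstm") {
    lstm_backward(l, dOut)
  } else if (l$type == "gru") {
    gru_backward(l, dOut)
  } else stop("unknown layer type ", l$type)
}

# ---- recurrent cells ---------------------------------------------------------

lstm_forward <- function(l, X) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; u <- l$units
  h <- matrix(0, B, u); cst <- matrix(0, B, u)
  Hs <- array(0, c(B, Tn, u))
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B)
    A <- sweep(Xt %*% l$Wx + h %*% l$Wh, 2, l$b, "+")
    i <- sigmoid(A[, 1:u, drop = FALSE])
    f <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
    o <- sigmoid(A[, (2 * u + 1):(3 * u), drop = FALSE])
    g <- tanh(A[, (3 * u + 1):(4 * u), drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    Hs[, t, ] <- h
    cache[[t]] <- list(Xt = Xt, h_prev = h_prev, c_prev = c_prev,
                       i = i, f = f, o = o, g = g, tc = tc)
  }
  l$cache <- list(cells = cache, X_dim = dim(X))
  if (l$return_sequences) Hs else h
}

lstm_backward <- function(l, dOut) {
  cache <- l$cache$cells
  Xd <- l$cache$X_dim
  B <- Xd[1]; Tn <- Xd[2]; u <- l$units
  ret_seq <- l$return_sequences
  gWx <- matrix(0, nrow(l$Wx), ncol(l$Wx))
  gWh <- matrix(0, nrow(l$Wh), ncol(l$Wh))
  gb <- rep(0, length(l$b))
  dX <- array(0, Xd)
  dh <- if (ret_seq) matrix(0, B, u) else dOut
  dc <- matrix(0, B, u)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    if (ret_seq) dh <- dh + matrix(dOut[, t, ], B)
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g; dg <- dc * cc$i; df <- dc * cc$c_prev
    dc <- dc * cc$f
    dA <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    gWx <- gWx + crossprod(cc$Xt, dA)
    gWh <- gWh + crossprod(cc$h_prev, dA)
    gb <- gb + colSums(dA)
    dX[, t, ] <- dA %*% t(l$Wx)
    dh <- dA %*% t(l$Wh)
  }
  l$gWx <- gWx; l$gWh <- gWh; l$gb <- gb
  dX
}

gru_forward <- function(l, X) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; u <- l$units
  h <- matrix(0, B, u)
  Hs <- array(0, c(B, Tn, u))
  cache <- vector("list", Tn)
  iz <- 1:u; ir <- (u + 1):(2 * u); inn <- (2 * u + 1):(3 * u)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B)
    Ax <- sweep(Xt %*% l$Wx, 2, l$b, "+")
    Ah <- h %*% l$Wh
    z <- sigmoid(Ax[, iz, drop = FALSE] + Ah[, iz, drop = FALSE])
    r <- sigmoid(Ax[, ir, drop = FALSE] + Ah[, ir, drop = FALSE])
    rh <- r * h
    n <- tanh(Ax[, inn, drop = FALSE] + rh %*% l$Wh[, inn, drop = FALSE])
    h_prev <- h
    h <- (1 - z) * n + z * h_prev
    Hs[, t, ] <- h
    cache[[t]] <- list(Xt = Xt, h_prev = h_prev, z = z, r = r, n = n, rh = rh)
  }
  l$cache <- list(cells = cache, X_dim = dim(X))
  if (l$return_sequences) Hs else h
}

gru_backward <- function(l, dOut) {
  cache <- l$cache$cells
  Xd <- l$cache$X_dim
  B <- Xd[1]; Tn <- Xd[2]; u <- l$units
  ret_seq <- l$return_sequences
  iz <- 1:u; ir <- (u + 1):(2 * u); inn <- (2 * u + 1):(3 * u)
  gWx <- matrix(0, nrow(l$Wx), ncol(l$Wx))
  gWh <- matrix(0, nrow(l$Wh), ncol(l$Wh))
  gb <- rep(0, length(l$b))
  dX <- array(0, Xd)
  dh <- if (ret_seq) matrix(0, B, u) else dOut
  Whn <- l$Wh[, inn, drop = FALSE]
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    if (ret_seq) dh <- dh + matrix(dOut[, t, ], B)
    dn <- dh * (1 - cc$z)
    dz <- dh * (cc$h_prev - cc$n)
    dh_prev <- dh * cc$z
    dan <- dn * (1 - cc$n^2)
    drh <- dan %*% t(Whn)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    dA <- cbind(daz, dar, dan)
    gWx <- gWx + crossprod(cc$Xt, dA)
    gb <- gb + colSums(dA)
    gWh[, iz] <- gWh[, iz] + crossprod(cc$h_prev, daz)
    gWh[, ir] <- gWh[, ir] + crossprod(cc$h_prev, dar)
    gWh[, inn] <- gWh[, inn] + crossprod(cc$rh, dan)
    dh_prev <- dh_prev + daz %*% t(l$Wh[, iz, drop = FALSE]) +
      dar %*% t(l$Wh[, ir, drop = FALSE])
    dX[, t, ] <- dA %*% t(l$Wx)
    dh <- dh_prev
  }
  l$gWx <- gWx; l$gWh <- gWh; l$gb <- gb
  dX
}

# ---- forward / loss ----------------------------------------------------------

nn_forward <- function(net, X, training = FALSE) {
  out <- X
  for (l in net$layers) out <- layer_forward(l, out, training = training)
  out
}

nn_forward_to <- function(net, X, layer_name) {
  out <- X
  for (l in net$layers) {
    out <- layer_forward(l, out, training = FALSE)
    if (!is.null(l$name) && identical(l$name, layer_name)) return(out)
  }
  stop("no layer named ", layer_name)
}

# loss and gradient at the (linear) output; bce applies the sigmoid itself
nn_loss_grad <- function(net, Z, y) {
  B <- nrow(Z)
  if (net$loss == "bce") {
    p <- sigmoid(Z)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    grad <- (p - y) / B
  } else {
    loss <- mean((Z - y)^2)
    grad <- 2 * (Z - y) / (B * ncol(Z))
  }
  list(loss = loss, grad = grad)
}

nn_backward <- function(net, dOut) {
  force(dOut)   # the gradient argument may embed the forward pass; run it
                # before any layer cache is read
  for (l in rev(net$layers)) {
    dOut <- layer_backward(l, dOut)
    if (is.null(dOut) && !identical(l, net$layers[[1]])) {
      stop("gradient chain broke before the first layer")
    }
  }
  invisible(dOut)   # gradient w.r.t. the network input (NULL after embeddings)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(net) {
  st <- list()
  for (k in seq_along(net$layers)) {
    l <- net$layers[[k]]
    for (p in layer_param_names(l)) {
      key <- paste0(k, ".", p)
      st[[key]] <- list(m = l[[p]] * 0, v = l[[p]] * 0)
    }
  }
  net$adam <- list(state = st, t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
  invisible(net)
}

adam_step <- function(net, lr) {
  ad <- net$adam
  ad$t <- ad$t + 1
  for (k in seq_along(net$layers)) {
    l <- net$layers[[k]]
    for (p in layer_param_names(l)) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      key <- paste0(k, ".", p)
      s <- ad$state[[key]]
      s$m <- ad$beta1 * s$m + (1 - ad$beta1) * g
      s$v <- ad$beta2 * s$v + (1 - ad$beta2) * g^2
      mhat <- s$m / (1 - ad$beta1^ad$t)
      vhat <- s$v / (1 - ad$beta2^ad$t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + ad$eps)
      ad$state[[key]] <- s
    }
  }
  net$adam <- ad
  invisible(net)
}

# ---- training loop -----------------------------------------------------------

# Stratified validation split, Adam updates in mini-batches, learning-rate
# decay by `lr_decay_factor` when the validation loss plateaus for
# `plateau_patience` epochs, stop at the second plateau. With
# `init_output_bias` the final layer's bias starts at log(p1/p0) so initial
# predictions reflect the class ratio.
nn_fit <- function(net, X, y, epochs = 100, batch_size = 32,
                   validation_fraction = 0.1, lr = 1e-3,
                   plateau_patience = 10, lr_decay_factor = 10,
                   init_output_bias = FALSE, verbose = FALSE, seed = NULL) {
  seed <- seed %||% net$seed
  is_seq <- is.array(X) && length(dim(X)) == 3
  n <- if (is.matrix(X) || is_seq) dim(X)[1] else nrow(X)
  y <- as.matrix(y)
  withr::with_seed(seed, {
    if (init_output_bias && net$loss == "bce") {
      p1 <- mean(y[, 1])
      p1 <- min(max(p1, 1e-6), 1 - 1e-6)
      last <- net$layers[[length(net$layers)]]
      last$b <- rep(log(p1 / (1 - p1)), length(last$b))
      last$W[] <- 0   # initial prediction is exactly the class ratio
    }
    if (validation_fraction > 0) {
      val_idx <- stratified_indices(y[, 1], validation_fraction)
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    take <- function(idx) {
      if (is_seq || (is.matrix(X) && !is.null(dim(X)))) {
        if (is_seq) X[idx, , , drop = FALSE] else X[idx, , drop = FALSE]
      } else X[idx]
    }
    Xtr <- take(tr_idx); ytr <- y[tr_idx, , drop = FALSE]
    Xva <- take(val_idx); yva <- y[val_idx, , drop = FALSE]

    adam_init(net)
    best <- Inf; since_best <- 0L; plateaus <- 0L
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(tr_idx))
      tot <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        Xb <- if (is_seq) Xtr[bi, , , drop = FALSE] else Xtr[bi, , drop = FALSE]
        Z <- nn_forward(net, Xb, training = TRUE)
        lg <- nn_loss_grad(net, Z, ytr[bi, , drop = FALSE])
        if (!is.finite(lg$loss)) {
          stop("nn_fit: non-finite training loss at epoch ", ep,
               " (lr = ", lr, ")")
        }
        nn_backward(net, lg$grad)
        adam_step(net, lr)
        tot <- tot + lg$loss; nb <- nb + 1
      }
      val_loss <- if (length(val_idx)) {
        Zv <- nn_forward(net, Xva, training = FALSE)
        nn_loss_grad(net, Zv, yva)$loss
      } else tot / nb
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tot / nb,
                                   val_loss = val_loss, lr = lr)
      if (verbose) {
        message(sprintf("epoch %d train %.4f val %.4f lr %.2g",
                        ep, tot / nb, val_loss, lr))
      }
      if (val_loss < best - 1e-6) {
        best <- val_loss; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= plateau_patience) {
          plateaus <- plateaus + 1L
          since_best <- 0L
          if (plateaus >= 2L) break       # second plateau: stop
          lr <- lr / lr_decay_factor      # first plateau: decay
        }
      }
    }
    dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  })
}

stratified_indices <- function(y, fraction) {
  idx <- integer(0)
  for (cl in unique(y)) {
    members <- which(y == cl)
    k <- max(1L, round(length(members) * fraction))
    idx <- c(idx, sample(members, min(k, length(members))))
  }
  sort(idx)
}

nn_predict_prob <- function(net, X) {
  Z <- nn_forward(net, X, training = FALSE)
  if (net$loss == "bce") as.vector(sigmoid(Z)) else as.vector(Z)
}
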