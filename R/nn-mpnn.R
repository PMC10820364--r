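# Message-passing neural network on molecular graphs: T rounds in which each
# atom aggregates transformed messages from its neighbours (bond features
# included), a GRU-cell state update, mean readout over atoms, dense head.
# Message/update weights are shared across rounds.

# assemble a batch of molecular_graph objects into flat node/edge tables;
# node features are scaled to comparable magnitudes
batch_graphs <- function(graphs) {
  nf <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  node_X <- cbind(
    nf[, "atomic_number"] / 54,
    nf[, "valence"] / 6,
    nf[, "n_hydrogens"] / 4,
    nf[, "hybridization"] / 3
  )
  sizes <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  graph_id <- rep(seq_along(graphs), sizes)
  src <- integer(0); dst <- integer(0); eo <- numeric(0); ec <- numeric(0)
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    if (nrow(g$edges)) {
      a1 <- g$edges[, 1] + offset[k]; a2 <- g$edges[, 2] + offset[k]
      src <- c(src, a1, a2); dst <- c(dst, a2, a1)   # messages both ways
      eo <- c(eo, rep(g$edge_features[, "bond_order"] / 3, 2))
      ec <- c(ec, rep(g$edge_features[, "conjugated"], 2))
    }
  }
  list(node_X = node_X, graph_id = graph_id, n_graphs = length(graphs),
       src = src, dst = dst, edge_X = cbind(eo, ec))
}

mpnn_new <- function(hidden = 64, rounds = 3, head = c(64), node_dim = 4,
                     edge_dim = 2, seed = 1L) {
  net <- new.env(parent = emptyenv())
  net$hidden <- hidden; net$rounds <- rounds
  withr::with_seed(seed, {
    net$W_in <- glorot(node_dim, hidden); net$b_in <- rep(0, hidden)
    net$Wm <- glorot(hidden + edge_dim, hidden); net$bm <- rep(0, hidden)
    net$Wx <- glorot(hidden, 3 * hidden); net$Wh <- glorot(hidden, 3 * hidden)
    net$bg <- rep(0, 3 * hidden)
    dims <- c(hidden, head)
    net$head <- lapply(seq_len(length(dims) - 1), function(i) {
      init_layer(nn_dense(dims[i], dims[i + 1], activation = "relu"))
    })
    net$out <- init_layer(nn_dense(dims[length(dims)], 1, activation = "linear"))
  })
  net$loss <- "bce"
  net$seed <- as.integer(seed)
  class(net) <- "mpnn_net"
  net
}

mpnn_param_names <- c("W_in", "b_in", "Wm", "bm", "Wx", "Wh", "bg")

# one GRU-cell step (input M, hidden h); returns new h and the cache
gru_cell_forward <- function(net, M, h) {
  u <- net$hidden
  iz <- 1:u; ir <- (u + 1):(2 * u); inn <- (2 * u + 1):(3 * u)
  Ax <- sweep(M %*% net$Wx, 2, net$bg, "+")
  Ah <- h %*% net$Wh
  z <- sigmoid(Ax[, iz, drop = FALSE] + Ah[, iz, drop = FALSE])
  r <- sigmoid(Ax[, ir, drop = FALSE] + Ah[, ir, drop = FALSE])
  rh <- r * h
  n <- tanh(Ax[, inn, drop = FALSE] + rh %*% net$Wh[, inn, drop = FALSE])
  h_new <- (1 - z) * n + z * h
  list(h = h_new, cache = list(M = M, h_prev = h, z = z, r = r, n = n, rh = rh))
}

gru_cell_backward <- function(net, dh, cc, grads) {
  u <- net$hidden
  iz <- 1:u; ir <- (u + 1):(2 * u); inn <- (2 * u + 1):(3 * u)
  dn <- dh * (1 - cc$z)
  dz <- dh * (cc$h_prev - cc$n)
  dh_prev <- dh * cc$z
  dan <- dn * (1 - cc$n^2)
  drh <- dan %*% t(net$Wh[, inn, drop = FALSE])
  dr <- drh * cc$h_prev
  dh_prev <- dh_prev + drh * cc$r
  daz <- dz * cc$z * (1 - cc$z)
  dar <- dr * cc$r * (1 - cc$r)
  dA <- cbind(daz, dar, dan)
  grads$Wx <- grads$Wx + crossprod(cc$M, dA)
  grads$bg <- grads$bg + colSums(dA)
  grads$Wh[, iz] <- grads$Wh[, iz] + crossprod(cc$h_prev, daz)
  grads$Wh[, ir] <- grads$Wh[, ir] + crossprod(cc$h_prev, dar)
  grads$Wh[, inn] <- grads$Wh[, inn] + crossprod(cc$rh, dan)
  dh_prev <- dh_prev + daz %*% t(net$Wh[, iz, drop = FALSE]) +
    dar %*% t(net$Wh[, ir, drop = FALSE])
  dM <- dA %*% t(net$Wx)
  list(dM = dM, dh_prev = dh_prev, grads = grads)
}

mpnn_forward <- function(net, batch, training = FALSE) {
  N <- nrow(batch$node_X)
  Z_in <- sweep(batch$node_X %*% net$W_in, 2, net$b_in, "+")
  h <- pmax(Z_in, 0)
  rounds <- vector("list", net$rounds)
  if (net$rounds > 0) {
    for (t in seq_len(net$rounds)) {
      cacheR <- list(h_before = h)
      if (length(batch$src)) {
        He <- cbind(h[batch$src, , drop = FALSE], batch$edge_X)
        A <- sweep(He %*% net$Wm, 2, net$bm, "+")
        Ar <- pmax(A, 0)
        M <- matrix(0, N, net$hidden)
        agg <- rowsum(Ar, group = batch$dst)
        M[as.integer(rownames(agg)), ] <- agg
      } else {
        A <- NULL; M <- matrix(0, N, net$hidden)
      }
      gc_ <- gru_cell_forward(net, M, h)
      h <- gc_$h
      cacheR$A <- A; cacheR$gru <- gc_$cache
      rounds[[t]] <- cacheR
    }
  }
  counts <- as.vector(table(factor(batch$graph_id, levels = seq_len(batch$n_graphs))))
  G <- rowsum(h, group = batch$graph_id) / counts
  a <- G
  for (l in net$head) a <- layer_forward(l, a, training = training)
  Z <- layer_forward(net$out, a, training = training)
  net$cache <- list(batch = batch, Z_in = Z_in, rounds = rounds,
                    h_final = h, counts = counts)
  Z
}

mpnn_backward <- function(net, dZ) {
  cache <- net$cache
  batch <- cache$batch
  N <- nrow(batch$node_X)
  d <- layer_backward(net$out, dZ)
  for (l in rev(net$head)) d <- layer_backward(l, d)
  dH <- d[batch$graph_id, , drop = FALSE] / cache$counts[batch$graph_id]

  grads <- list(
    W_in = net$W_in * 0, b_in = net$b_in * 0, Wm = net$Wm * 0, bm = net$bm * 0,
    Wx = net$Wx * 0, Wh = net$Wh * 0, bg = net$bg * 0
  )
  dh <- dH
  if (net$rounds > 0) {
    for (t in rev(seq_len(net$rounds))) {
      rc <- cache$rounds[[t]]
      gb <- gru_cell_backward(net, dh, rc$gru, grads)
      grads <- gb$grads
      dh <- gb$dh_prev
      if (length(batch$src)) {
        dAr <- gb$dM[batch$dst, , drop = FALSE]
        dA <- dAr * (rc$A > 0)
        He <- cbind(rc$h_before[batch$src, , drop = FALSE], batch$edge_X)
        grads$Wm <- grads$Wm + crossprod(He, dA)
        grads$bm <- grads$bm + colSums(dA)
        dHe <- dA %*% t(net$Wm)
        dh_src <- dHe[, seq_len(net$hidden), drop = FALSE]
        add <- rowsum(dh_src, group = batch$src)
        dh_acc <- matrix(0, N, net$hidden)
        dh_acc[as.integer(rownames(add)), ] <- add
        dh <- dh + dh_acc
      }
    }
  }
  dZ_in <- dh * (cache$Z_in > 0)
  grads$W_in <- crossprod(batch$node_X, dZ_in)
  grads$b_in <- colSums(dZ_in)
  net$grads <- grads
  invisible(NULL)
}

mpnn_fit <- function(net, graphs, y, epochs = 60, batch_size = 32,
                     validation_fraction = 0.1, lr = 1e-3,
                     plateau_patience = 10, lr_decay_factor = 10,
                     init_output_bias = TRUE, seed = NULL, verbose = FALSE) {
  seed <- seed %||% net$seed
  y <- as.numeric(y)
  n <- length(graphs)
  withr::with_seed(seed, {
    if (init_output_bias) {
      p1 <- min(max(mean(y), 1e-6), 1 - 1e-6)
      net$out$b <- rep(log(p1 / (1 - p1)), 1)
      net$out$W[] <- 0
    }
    val_idx <- if (validation_fraction > 0) {
      stratified_indices(y, validation_fraction)
    } else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    adam <- mpnn_adam_init(net)
    best <- Inf; since_best <- 0L; plateaus <- 0L
    hist <- list()
    val_batch <- if (length(val_idx)) batch_graphs(graphs[val_idx]) else NULL
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      tot <- 0; nb <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        bt <- batch_graphs(graphs[bi])
        Z <- mpnn_forward(net, bt, training = TRUE)
        lg <- nn_loss_grad(net, Z, matrix(y[bi], ncol = 1))
        if (!is.finite(lg$loss)) stop("mpnn_fit: non-finite loss at epoch ", ep)
        mpnn_backward(net, lg$grad)
        adam <- mpnn_adam_step(net, adam, lr)
        tot <- tot + lg$loss; nb <- nb + 1
      }
      val_loss <- if (!is.null(val_batch)) {
        Zv <- mpnn_forward(net, val_batch, training = FALSE)
        nn_loss_grad(net, Zv, matrix(y[val_idx], ncol = 1))$loss
      } else tot / nb
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tot / nb,
                                   val_loss = val_loss, lr = lr)
      if (verbose) message(sprintf("mpnn epoch %d val %.4f", ep, val_loss))
      if (val_loss < best - 1e-6) {
        best <- val_loss; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= plateau_patience) {
          plateaus <- plateaus + 1L; since_best <- 0L
          if (plateaus >= 2L) break
          lr <- lr / lr_decay_factor
        }
      }
    }
    dplyr::bind_rows(hist)
  })
}

mpnn_adam_init <- function(net) {
  st <- list()
  for (p in mpnn_param_names) st[[p]] <- list(m = net[[p]] * 0, v = net[[p]] * 0)
  head_layers <- c(net$head, list(net$out))
  for (k in seq_along(head_layers)) {
    for (p in c("W", "b")) {
      st[[paste0("head", k, ".", p)]] <-
        list(m = head_layers[[k]][[p]] * 0, v = head_layers[[k]][[p]] * 0)
    }
  }
  list(state = st, t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

mpnn_adam_step <- function(net, adam, lr) {
  adam$t <- adam$t + 1
  upd <- function(val, g, key) {
    s <- adam$state[[key]]
    s$m <- adam$beta1 * s$m + (1 - adam$beta1) * g
    s$v <- adam$beta2 * s$v + (1 - adam$beta2) * g^2
    adam$state[[key]] <<- s
    val - lr * (s$m / (1 - adam$beta1^adam$t)) /
      (sqrt(s$v / (1 - adam$beta2^adam$t)) + adam$eps)
  }
  for (p in mpnn_param_names) net[[p]] <- upd(net[[p]], net$grads[[p]], p)
  head_layers <- c(net$head, list(net$out))
  for (k in seq_along(head_layers)) {
    l <- head_layers[[k]]
    l$W <- upd(l$W, l$gW, paste0("head", k, ".W"))
    l$b <- upd(l$b, l$gb, paste0("head", k, ".b"))
  }
  adam
}

mpnn_predict_prob <- function(net, graphs) {
  bt <- batch_graphs(graphs)
  as.vector(sigmoid(mpnn_forward(net, bt, training = FALSE)))
}
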