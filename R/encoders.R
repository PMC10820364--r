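# The five chemical representations: molecular descriptors, circular
# (Morgan-style) fingerprints, MACCS key fingerprints, molecular graphs,
# tokenized SMILES, and latent codes, plus feature preprocessing for the
# dense encoders.

new_feature_bundle <- function(encoder_name, matrix, feature_names,
                               compounds, fitted_preprocess = NULL) {
  colnames(matrix) <- feature_names
  rownames(matrix) <- NULL
  structure(list(
    encoder_name = encoder_name,
    matrix = matrix,
    feature_names = feature_names,
    compounds = compounds,
    fitted_preprocess = fitted_preprocess
  ), class = "feature_bundle")
}

#' @exportS3Method base::print
print.feature_bundle <- function(x, ...) {
  cat("<feature_bundle>", x$encoder_name, ":",
      nrow(x$matrix), "compounds x", ncol(x$matrix), "features",
      if (!is.null(x$fitted_preprocess)) "(preprocessed)" else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_bundle <- function(x, ...) {
  df <- as.data.frame(x$matrix)
  df$compound <- x$compounds
  df[, c("compound", x$feature_names)]
}

compound_smiles <- function(compounds) {
  if (is.data.frame(compounds)) {
    col <- intersect(c("canonical_smiles", "compound", "smiles"), names(compounds))[1]
    if (is.na(col)) stop("no SMILES column found (expected canonical_smiles/compound/smiles)")
    as.character(compounds[[col]])
  } else {
    as.character(compounds)
  }
}

#' Compute 1-2D molecular descriptors
#'
#' One row per compound over the package's fixed descriptor set
#' (constitutional counts, topological indices, 2D autocorrelations,
#' atom-type counts, OpenBabel physico-chemical properties). Calculation
#' failures become `NA` cells for [preprocess_features()] to handle.
#'
#' @param compounds Data frame with a `canonical_smiles` column, or a
#'   character vector of SMILES.
#' @return A `feature_bundle` with `encoder_name = "descriptors"`.
#' @export
compute_descriptors <- function(compounds) {
  smi <- compound_smiles(compounds)
  nm <- descriptor_names()
  graph_names <- setdiff(nm, c("logP", "TPSA", "MR", "HBA1", "HBA2", "HBD_jl"))
  mat <- matrix(NA_real_, length(smi), length(nm), dimnames = list(NULL, nm))
  ok <- which(!is.na(smi) & nzchar(smi))
  if (length(ok)) {
    mols <- parse_molecules(smi[ok])
    for (k in seq_along(ok)) {
      row <- tryCatch(descriptors_one(mols[[k]]), error = function(e) NULL)
      if (!is.null(row)) mat[ok[k], graph_names] <- row[graph_names]
    }
    mat[ok, c("logP", "TPSA", "MR", "HBA1", "HBA2", "HBD_jl")] <- ob_physchem(smi[ok])
  }
  new_feature_bundle("descriptors", mat, nm, smi)
}

# fold a wide bit matrix down to n_bits by OR over congruent columns
fold_bits <- function(mat, n_bits) {
  p <- ncol(mat)
  if (p == n_bits) return(mat)
  stopifnot(p %% n_bits == 0)
  out <- matrix(0L, nrow(mat), n_bits)
  for (k in seq_len(p / n_bits)) {
    blk <- mat[, ((k - 1) * n_bits + 1):(k * n_bits), drop = FALSE]
    out <- pmax(out, blk)
  }
  out
}

#' Compute circular (extended-connectivity) fingerprints
#'
#' Hashed atom-environment fingerprints enumerating all circular fragments up
#' to the given radius, folded to `n_bits` columns.
#'
#' @inheritParams compute_descriptors
#' @param radius Maximum environment radius in bonds (default 2, the
#'   ECFP4-equivalent setting).
#' @param n_bits Folded fingerprint width (default 2048).
#' @return A `feature_bundle` with `encoder_name = "circular_fp"`.
#' @export
compute_circular_fp <- function(compounds, radius = 2, n_bits = 2048) {
  stopifnot(radius >= 0, n_bits >= 8)
  smi <- compound_smiles(compounds)
  type <- paste0("ECFP", 2 * radius)
  if (!type %in% names(FP_NBITS)) {
    stop("unsupported radius ", radius, " (0-5 available)")
  }
  raw <- ob_fingerprint_matrix(smi, type)
  nb <- min(n_bits, ncol(raw))
  mat <- fold_bits(raw, nb)
  if (nb < n_bits) mat <- cbind(mat, matrix(0L, nrow(mat), n_bits - nb))
  new_feature_bundle("circular_fp", mat, paste0("fp", seq_len(n_bits)), smi)
}

#' Compute MACCS structural-key fingerprints
#'
#' Presence/absence of the 166 public MACCS structural keys.
#'
#' @inheritParams compute_descriptors
#' @return A `feature_bundle` with `encoder_name = "maccs_fp"`.
#' @export
compute_maccs_fp <- function(compounds) {
  smi <- compound_smiles(compounds)
  raw <- ob_fingerprint_matrix(smi, "MACCS")
  mat <- raw[, seq_len(166), drop = FALSE]
  new_feature_bundle("maccs_fp", mat, paste0("maccs", seq_len(166)), smi)
}

#' Build molecular graphs for graph neural networks
#'
#' Each heavy atom becomes a node with features (atomic number, valence,
#' bonded hydrogen count, hybridization code); bonds become undirected edges
#' (stored once, as index pairs) with bond-order and conjugation features.
#'
#' @inheritParams compute_descriptors
#' @return A list of `molecular_graph` objects, one per compound.
#' @export
featurize_graph <- function(compounds) {
  smi <- compound_smiles(compounds)
  mols <- parse_molecules(smi)
  purrr::map2(mols, smi, function(m, s) {
    nf <- cbind(
      atomic_number = m$atoms$atomic_number,
      valence = m$atoms$valence,
      n_hydrogens = m$atoms$n_hydrogens,
      hybridization = m$atoms$hybridization
    )
    ef <- cbind(
      bond_order = m$bonds$order,
      conjugated = as.integer(m$bonds$conjugated)
    )
    structure(list(
      smiles = s,
      node_features = nf,
      edges = cbind(a1 = m$bonds$a1, a2 = m$bonds$a2),
      edge_features = ef
    ), class = "molecular_graph")
  })
}

#' @exportS3Method base::print
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", x$smiles, ":", nrow(x$node_features), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# ---- SMILES tokenization -----------------------------------------------------

PAD_TOKEN <- "<pad>"
UNK_TOKEN <- "<unk>"
SEQ_TOKEN <- "<s>"

#' Build a character vocabulary from a SMILES corpus
#'
#' Characters are single SMILES characters (multi-letter element symbols are
#' split, matching character-level vectorization). The output length is the
#' nearest-rank percentile of corpus string lengths.
#'
#' @param smiles_corpus Character vector of SMILES strings.
#' @param length_percentile Percentile (nearest rank) fixing the padded
#'   sequence length (default 95).
#' @return A `smiles_vocabulary`: `characters` (specials first), and
#'   `output_length`.
#' @export
build_vocabulary <- function(smiles_corpus, length_percentile = 95) {
  smiles_corpus <- smiles_corpus[!is.na(smiles_corpus)]
  if (!length(smiles_corpus)) stop("build_vocabulary: empty corpus")
  chars <- sort(unique(unlist(strsplit(smiles_corpus, ""))))
  lens <- sort(nchar(smiles_corpus))
  rank <- ceiling(length_percentile / 100 * length(lens))
  rank <- min(max(rank, 1L), length(lens))
  structure(list(
    characters = c(PAD_TOKEN, UNK_TOKEN, SEQ_TOKEN, chars),
    output_length = as.integer(lens[rank])
  ), class = "smiles_vocabulary")
}

#' @exportS3Method base::print
print.smiles_vocabulary <- function(x, ...) {
  cat("<smiles_vocabulary>", length(x$characters), "tokens (",
      length(x$characters) - 3, "characters + 3 specials ), output length",
      x$output_length, "\n")
  invisible(x)
}

#' Vectorize SMILES against a vocabulary
#'
#' Per-character integer ids, truncated or right-padded to the vocabulary's
#' output length. Characters unseen at build time map to the reserved
#' unknown id.
#'
#' @param smiles Character vector.
#' @param vocab A [build_vocabulary()] result.
#' @return Integer matrix, `length(smiles)` x `output_length`; the pad id is
#'   1 (position of `"<pad>"`), ids are 1-based indices into
#'   `vocab$characters`.
#' @export
vectorize_smiles <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  L <- vocab$output_length
  pad_id <- 1L
  unk_id <- 2L
  lut <- stats::setNames(seq_along(vocab$characters), vocab$characters)
  out <- matrix(pad_id, length(smiles), L)
  for (i in seq_along(smiles)) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) next
    ch <- strsplit(smiles[i], "")[[1]]
    ids <- unname(lut[ch])
    ids[is.na(ids)] <- unk_id
    k <- min(length(ids), L)
    out[i, seq_len(k)] <- ids[seq_len(k)]
  }
  out
}

#' Recover the character prefix encoded by token ids
#'
#' @param ids Integer vector of token ids.
#' @param vocab The vocabulary used to produce them.
#' @return Single string (pad/unknown tokens dropped).
#' @export
devectorize_smiles <- function(ids, vocab) {
  ch <- vocab$characters[ids]
  paste(ch[!ch %in% c(PAD_TOKEN, UNK_TOKEN, SEQ_TOKEN)], collapse = "")
}

# ---- latent encoders ---------------------------------------------------------

#' Deterministic hashed n-gram latent encoder
#'
#' A training-free latent representation: character n-gram counts of the
#' SMILES string are hashed into `width` signed buckets and L2-normalized.
#' Deterministic given the seed built into the hash.
#'
#' @param width Output dimension (default 128).
#' @param ngrams Integer vector of n-gram sizes (default 1:3).
#' @return A `latent_encoder` handle usable with [latent_encode()].
#' @export
latent_encoder_hash <- function(width = 128, ngrams = 1:3) {
  structure(list(kind = "hash", width = as.integer(width), ngrams = ngrams),
            class = "latent_encoder")
}

#' Trainable autoencoder latent encoder
#'
#' Compresses hashed n-gram profiles through a dense autoencoder trained on a
#' SMILES corpus (squared-error reconstruction); the bottleneck activations
#' are the latent code. A light-weight stand-in for pretrained
#' sequence-autoencoder descriptors, trainable on any corpus.
#'
#' @param corpus Character vector of training SMILES.
#' @param width Latent dimension (default 64).
#' @param input_width Hashed input dimension (default 512).
#' @param epochs,seed Training epochs and seed.
#' @return A fitted `latent_encoder` handle.
#' @export
latent_encoder_autoencoder <- function(corpus, width = 64, input_width = 512,
                                       epochs = 30, seed = 1L) {
  X <- hash_ngram_matrix(corpus, input_width, 1:3)
  net <- nn_sequential(
    list(
      nn_dense(input_width, 128, activation = "relu"),
      nn_dense(128, width, activation = "tanh", name = "latent"),
      nn_dense(width, 128, activation = "relu"),
      nn_dense(128, input_width, activation = "linear")
    ),
    loss = "mse", seed = seed
  )
  hist <- nn_fit(net, X, X, epochs = epochs, batch_size = 32,
                 validation_fraction = 0, lr = 1e-3, verbose = FALSE)
  structure(list(kind = "autoencoder", width = as.integer(width),
                 input_width = as.integer(input_width), net = net,
                 history = hist),
            class = "latent_encoder")
}

#' Encode compounds with a latent encoder handle
#'
#' @inheritParams compute_descriptors
#' @param encoder A `latent_encoder` (see [latent_encoder_hash()],
#'   [latent_encoder_autoencoder()]); any object with a
#'   `predict(encoder, smiles)` method returning a fixed-width numeric
#'   matrix also works.
#' @return A `feature_bundle` with `encoder_name = "latent"`.
#' @export
latent_encode <- function(compounds, encoder = latent_encoder_hash()) {
  if (missing(encoder) || is.null(encoder)) {
    stop("latent_encode: no encoder handle supplied; use latent_encoder_hash() ",
         "for the deterministic surrogate or latent_encoder_autoencoder() ",
         "to train one on your corpus")
  }
  smi <- compound_smiles(compounds)
  mat <- predict(encoder, smi)
  new_feature_bundle("latent", mat, paste0("z", seq_len(ncol(mat))), smi)
}

#' @export
predict.latent_encoder <- function(object, newdata, ...) {
  smi <- compound_smiles(newdata)
  if (object$kind == "hash") {
    hash_ngram_matrix(smi, object$width, object$ngrams)
  } else {
    X <- hash_ngram_matrix(smi, object$input_width, 1:3)
    nn_forward_to(object$net, X, layer_name = "latent")
  }
}

# signed feature hashing of character n-grams (FNV-style rolling hash);
# raw signed counts, so downstream variance/correlation pruning and
# standardization see a natural scale
hash_ngram_matrix <- function(smiles, width, ngrams) {
  out <- matrix(0, length(smiles), width)
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(s)) next
    ch <- utf8ToInt(s)
    v <- numeric(width)
    for (n in ngrams) {
      if (length(ch) < n) next
      h <- rep(2166136261, length(ch) - n + 1)
      for (k in seq_len(n)) {
        h <- (h * 16777619 + ch[k:(length(ch) - n + k)]) %% 2^31
      }
      bucket <- (h %% width) + 1
      sign <- ifelse((h %/% width) %% 2 == 0, 1, -1)
      for (j in seq_along(bucket)) v[bucket[j]] <- v[bucket[j]] + sign[j]
    }
    out[i, ] <- v
  }
  out
}

# ---- feature preprocessing ---------------------------------------------------

#' Fit and apply feature preprocessing (descriptors and latent codes)
#'
#' On the training bundle: drop features with variance below `min_variance`,
#' greedily drop one of each pair with |Pearson r| above `max_correlation`
#' (features visited by descending variance; the later feature of an
#' offending pair is dropped), impute remaining missing cells with the
#' training median, and standardize to zero mean / unit variance. The fitted
#' transform is applied unchanged to any held-out bundles; no held-out
#' statistic influences it.
#'
#' @param train_bundle A `feature_bundle` (training compounds).
#' @param ... Further bundles (validation/test) to transform with the fitted
#'   state.
#' @param min_variance,max_correlation Thresholds (defaults 0.1 and 0.9).
#' @return The transformed training bundle, or a list of transformed bundles
#'   (training first) when `...` is non-empty.
#' @export
preprocess_features <- function(train_bundle, ..., min_variance = 0.1,
                                max_correlation = 0.9) {
  stopifnot(inherits(train_bundle, "feature_bundle"))
  X <- train_bundle$matrix
  if (!nrow(X)) stop("preprocess_features: empty training matrix")
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  keep <- v >= min_variance
  if (!any(keep)) stop("preprocess_features: all features dropped by the variance filter")

  kept_idx <- which(keep)
  ord <- kept_idx[order(v[kept_idx], decreasing = TRUE)]
  Xk <- X[, ord, drop = FALSE]
  cm <- suppressWarnings(stats::cor(Xk, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  drop <- rep(FALSE, ncol(Xk))
  for (j in seq_len(ncol(Xk))) {
    if (drop[j]) next
    if (j < ncol(Xk)) {
      worse <- which(abs(cm[j, (j + 1):ncol(Xk)]) > max_correlation) + j
      drop[worse] <- TRUE
    }
  }
  final_idx <- sort(ord[!drop])
  if (!length(final_idx)) stop("preprocess_features: all features dropped")

  Xf <- X[, final_idx, drop = FALSE]
  med <- apply(Xf, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(Xf))) Xf[is.na(Xf[, j]), j] <- med[j]
  mu <- colMeans(Xf)
  sd_ <- apply(Xf, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  fit <- list(
    keep_features = train_bundle$feature_names[final_idx],
    keep_index = final_idx, median = med, mean = mu, sd = sd_,
    min_variance = min_variance, max_correlation = max_correlation
  )
  out_train <- apply_preprocess(train_bundle, fit)
  others <- list(...)
  if (!length(others)) return(out_train)
  c(list(out_train), lapply(others, apply_preprocess, fit = fit))
}

apply_preprocess <- function(bundle, fit) {
  stopifnot(inherits(bundle, "feature_bundle"))
  if (!all(fit$keep_features %in% bundle$feature_names)) {
    stop("apply_preprocess: feature space mismatch")
  }
  X <- bundle$matrix[, fit$keep_features, drop = FALSE]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- fit$median[j]
  X <- sweep(sweep(X, 2, fit$mean, "-"), 2, fit$sd, "/")
  new_feature_bundle(bundle$encoder_name, X, fit$keep_features,
                     bundle$compounds, fitted_preprocess = fit)
}
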