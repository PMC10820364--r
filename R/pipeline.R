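# Configuration-driven orchestration of the full workflow:
# curate -> label -> split -> encode -> (augment / oversample) -> train ->
# applicability domain -> evaluate. One global seed expands into per-stage
# seeds by a fixed counter scheme so stages can be reproduced in isolation.

STAGE_SEED_OFFSET <- c(generate = 0L, curate = 1L, label = 2L, split = 3L,
                       encode = 4L, augment = 5L, oversample = 6L,
                       train = 7L, ad = 8L, evaluate = 9L)

stage_seed <- function(seed, stage) seed + 100L * STAGE_SEED_OFFSET[[stage]]

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file. See [run_pipeline()] for the recognized keys.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the modelling pipeline
#'
#' Orchestrates the full workflow from a configuration list (or YAML file
#' read by [read_pipeline_config()]):
#'
#' * `benchmark`: `preset` / `seed` / `label_noise` to generate a synthetic
#'   endpoint dataset, or `inputs`: paths `compounds`, `hitcalls`,
#'   `endpoint_config` plus `endpoint` to load real tables;
#' * `splits`: test fractions evaluated in series (default `0.1`);
#' * `models`: list of `{family, encoder}` entries;
#' * `imbalance`: oversampling config applied to baseline training data
#'   (`variant`, `k_neighbors`);
#' * `augment`: `{factor}` applied to the sequence model's training data;
#' * `ad`: `{methods}` for the applicability-domain consensus on the test
#'   set (tabular encoders in `models`);
#' * `train`: overrides for [train_config()];
#' * `seed`, `output_dir`.
#'
#' @param config Configuration list.
#' @return A `pipeline_result`: `metrics` (tidy tibble: model, encoder,
#'   split, partition, six metrics), `ad` (consensus tibble or NULL),
#'   `manifest` (inputs, seeds, artifact hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  t_start <- Sys.time()

  # ---- data stage
  if (!is.null(config$benchmark)) {
    if (!is.null(config$benchmark$n_active)) {
      cfg_syn <- synthetic_config(
        n_active = config$benchmark$n_active,
        n_inactive = config$benchmark$n_inactive,
        assay_specs = default_assay_specs(config$benchmark$n_assays %||% 3L),
        label_noise = config$benchmark$label_noise %||% 0,
        seed = stage_seed(seed, "generate")
      )
      lib <- generate_library(cfg_syn)
      dataset <- tibble::tibble(compound = lib$canonical_smiles,
                                active = lib$active)
      attr(dataset, "endpoint") <- config$endpoint %||% "custom"
      class(dataset) <- c("endpoint_dataset", class(dataset))
    } else {
      bm <- generate_benchmark(
        preset = config$benchmark$preset %||% "ke1_like",
        seed = stage_seed(seed, "generate"),
        label_noise = config$benchmark$label_noise %||% 0
      )
      dataset <- bm$dataset
    }
  } else if (!is.null(config$inputs)) {
    compounds <- read_compounds(config$inputs$compounds)
    curated <- curate_compounds(compounds)
    calls <- read_hitcalls(config$inputs$hitcalls)
    missing_cmp <- setdiff(calls$compound, curated$canonical_smiles)
    calls <- calls[!calls$compound %in% missing_cmp, , drop = FALSE]
    epmap <- read_endpoint_config(config$inputs$endpoint_config)
    ep <- config$endpoint %||% names(epmap)[1]
    if (!ep %in% names(epmap)) stop("run_pipeline: unknown endpoint ", ep)
    unknown <- setdiff(epmap[[ep]], names(calls))
    if (length(unknown)) {
      stop("run_pipeline: endpoint references unknown assay(s): ",
           paste(unknown, collapse = ", "))
    }
    dataset <- aggregate_hitcalls(calls, epmap[[ep]], endpoint = ep)
  } else {
    stop("run_pipeline: config needs either 'benchmark' or 'inputs'")
  }

  splits <- as.numeric(config$splits %||% 0.1)
  model_cfgs <- config$models %||% list(list(family = "rforest", encoder = "circular_fp"))
  tcfg_over <- config$train %||% list()
  tcfg <- do.call(train_config, tcfg_over[names(tcfg_over) %in%
                                            names(formals(train_config))])

  metrics <- list()
  ad_out <- NULL
  for (frac in splits) {
    sp <- stratified_split(dataset, frac, seed = stage_seed(seed, "split"))
    for (mc in model_cfgs) {
      fam <- mc$family
      enc <- mc$encoder %||% NULL
      spec <- model_spec(fam, enc, hyperparameters = mc$hyperparameters %||% list(),
                         seed = stage_seed(seed, "train"))
      res <- fit_and_score(spec, sp, config, tcfg, seed)
      metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
        tibble::tibble(family = fam,
                       encoder = paste(spec$encoders, collapse = "+"),
                       split = frac, partition = c("train", "test")),
        dplyr::bind_rows(res$train_metrics, res$test_metrics)
      )
    }
    if (!is.null(config$ad) && frac == splits[1]) {
      tab_encs <- unique(unlist(lapply(model_cfgs, function(m) m$encoder)))
      tab_encs <- intersect(tab_encs, TABULAR_ENCODERS)
      if (length(tab_encs)) {
        tb <- encode_bundles(sp$train, tab_encs)
        qb <- encode_bundles(sp$test, tab_encs, fit_from = tb)
        ad_out <- ad_consensus(tb$pp, qb$pp,
                               methods = config$ad$methods %||% AD_METHODS)
      }
    }
  }
  metrics <- dplyr::bind_rows(metrics)

  manifest <- list(
    seed = seed,
    stage_seeds = as.list(vapply(names(STAGE_SEED_OFFSET), stage_seed,
                                 integer(1), seed = seed)),
    n_compounds = nrow(dataset),
    endpoint = attr(dataset, "endpoint"),
    splits = splits,
    models = model_cfgs,
    started = format(t_start), finished = format(Sys.time())
  )
  out <- list(metrics = metrics, ad = ad_out, manifest = manifest)
  class(out) <- "pipeline_result"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    mpath <- file.path(config$output_dir, "metrics.tsv")
    utils::write.table(metrics, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ad_out)) {
      utils::write.table(ad_out$verdicts,
                         file.path(config$output_dir, "ad_verdicts.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest$artifact_hashes <- as.list(tools::md5sum(
      list.files(config$output_dir, full.names = TRUE, pattern = "\\.tsv$")))
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$endpoint %||% "?", ":",
      x$manifest$n_compounds, "compounds,",
      length(unique(x$metrics$family)), "model(s),",
      length(x$manifest$splits), "split(s)\n")
  print(x$metrics[x$metrics$partition == "test",
                  c("family", "encoder", "split", "balanced_accuracy", "f1")])
  invisible(x)
}

encode_bundles <- function(part, encoders, fit_from = NULL) {
  raw <- list(); pp <- list()
  for (enc in encoders) {
    bundle <- switch(enc,
      descriptors = compute_descriptors(part),
      circular_fp = compute_circular_fp(part),
      maccs_fp = compute_maccs_fp(part),
      latent = latent_encode(part, latent_encoder_hash())
    )
    raw[[enc]] <- bundle
    pp[[enc]] <- if (enc %in% c("descriptors", "latent")) {
      if (is.null(fit_from)) {
        preprocess_features(bundle)
      } else {
        apply_preprocess(bundle, fit_from$pp[[enc]]$fitted_preprocess)
      }
    } else {
      bundle
    }
  }
  list(raw = raw, pp = pp)
}

fit_and_score <- function(spec, sp, config, tcfg, seed) {
  fam <- spec$family
  prep_tr <- prepare_model_data(spec, sp$train)
  prep_te <- prepare_model_data(spec, sp$test, state = prep_tr$state)
  ytr <- sp$train$active; yte <- sp$test$active

  if (fam %in% c("logreg", "dtree", "rforest", "balanced_rforest",
                 "grad_boost", "svm", "knn", "gnb")) {
    Xtr <- prep_tr$data$X; Xte <- prep_te$data$X
    if (!is.null(config$imbalance)) {
      oc <- oversample_config(
        variant = config$imbalance$variant %||% "smote",
        k_neighbors = config$imbalance$k_neighbors %||% 5L,
        seed = stage_seed(seed, "oversample")
      )
      os <- oversample(Xtr, ytr, oc)
      Xtr_fit <- os$X; ytr_fit <- os$y
    } else {
      Xtr_fit <- Xtr; ytr_fit <- ytr
    }
    m <- build_model(spec)
    m <- train_model(m, list(X = Xtr_fit, y = ytr_fit))
    p_tr <- predict(m, Xtr); p_te <- predict(m, Xte)
  } else if (fam == "dnn") {
    m <- build_model(spec, input_dim = ncol(prep_tr$data$X))
    m <- train_model(m, prep_tr$data, tcfg)
    p_tr <- predict(m, prep_tr$data$X); p_te <- predict(m, prep_te$data$X)
  } else if (fam == "nlp_seq") {
    vocab <- prep_tr$state$vocab
    if (!is.null(config$augment)) {
      aug <- augment_training_set(sp$train,
                                  factor = config$augment$factor %||% 10,
                                  seed = stage_seed(seed, "augment"))
      tok_tr <- vectorize_smiles(aug$smiles, vocab)
      ytr_fit <- aug$active
    } else {
      tok_tr <- prep_tr$data$tokens
      ytr_fit <- ytr
    }
    m <- build_model(spec, vocab_size = length(vocab$characters))
    m <- train_model(m, list(tokens = tok_tr, y = ytr_fit), tcfg)
    p_tr <- predict(m, prep_tr$data$tokens); p_te <- predict(m, prep_te$data$tokens)
  } else if (fam == "mpnn") {
    m <- build_model(spec)
    m <- train_model(m, prep_tr$data, tcfg)
    p_tr <- predict(m, prep_tr$data$graphs); p_te <- predict(m, prep_te$data$graphs)
  } else {
    dims <- lapply(prep_tr$data[setdiff(MULTIMODAL_ENCODERS, "tokens")], ncol)
    m <- build_model(spec, vocab_size = length(prep_tr$state$vocab$characters),
                     branch_input_dims = dims)
    m <- train_model(m, prep_tr$data, tcfg)
    p_tr <- predict(m, prep_tr$data); p_te <- predict(m, prep_te$data)
  }
  list(train_metrics = compute_metrics(ytr, p_tr >= 0.5),
       test_metrics = compute_metrics(yte, p_te >= 0.5))
}
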