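# Synthetic benchmark generator: compound libraries with a planted
# toxicophore defining ground-truth activity, plus assay hit-call matrices
# with class-conditional hit probabilities. Emulates the size and imbalance
# of the three cardiotoxicity AOP endpoint datasets.

# Fragment grammar. Slot tokens {A}/{B}/{C} sit in branch "({X})" or suffix
# positions attached to carbon, so every decoration string is valid in every
# slot. Aromatic templates can host the (aromatic-ring) toxicophore in slot A.
AROMATIC_TEMPLATES <- c(
  "c1cc({A})ccc1{B}",
  "c1cc({A})cc({B})c1{C}",
  "c1c({A})cccc1C({B})C",
  "c1cc({A})ccc1C{B}",
  "c1cc({A})cc({B})n1",
  "c1cc({A})ccn1",
  "c1cc({A})c({B})o1",
  "c1cc({A})c({B})s1",
  "c1cc({A})c({B})[nH]1",
  "c1ccc2cc({A})ccc2c1{B}",
  "c1cc({A})ccc1-c1ccc({B})cc1",
  "c1cc({A})ccc1OC{B}",
  "c1cc({A})ccc1C=C{B}",
  "c1cc({A})ccc1NC(=O)C{B}",
  "c1cc({A})ccc1C(=O)OC{B}",
  "c1cc({A})ccc1C(=O)N{B}",
  "c1cc({A})ccc1S(=O)(=O)N{B}",
  "c1cc({A})ccc1CC({B})C(=O)O",
  "c1cc({A})ccc1CN(C)C{B}",
  "c1cc({A})ccc1C(C)({B})C",
  "c1cc({A})ccc1CC(=O)N{B}",
  "c1cc({A})ccc1OCC({B})O",
  "c1c({A})cc({B})cc1C{C}",
  "c1cc({A})c({B})cc1{C}",
  "c1cc({A})ccc1CC({B})C{C}",
  "c1cc({A})ccc1OC({B})C{C}",
  "c1cc({A})ccc1N(C{B})C{C}",
  "c1cc({A})ccc1-c1cc({B})cc({C})c1",
  "c1cc({A})ccc1C(=O)NC({B})C{C}",
  "c1cc({A})ccc1CCC({B})C{C}",
  "c1cc({A})ccc1C(C)({B})CC{C}",
  "c1cc({A})ccc1SCC({B})C{C}"
)
ALIPHATIC_TEMPLATES <- c(
  "C1CCC({A})CC1{B}",
  "C1CC({A})C({B})C1",
  "C1CCN(C(=O)C{A})CC1",
  "C1CCOC1C{A}",
  "CCC({A})CC{B}",
  "CC({A})CC({B})C",
  "CCCC({A})C(=O)O",
  "CC(C)C({A})CC(=O)N{B}",
  "C1CCC(CC1)CC({A})O",
  "CCOC(=O)C({A})C{B}",
  "CC(=O)NCC({A})C{B}",
  "C1CCCCC1CC({A})C(=O)OC"
)
DECORATIONS <- c(
  "", "C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC",
  "N(C)C", "F", "Cl", "Br", "I", "C#N", "C(=O)C", "C(=O)OC",
  "C(=O)O", "C(=O)N", "S(=O)(=O)N", "SC", "CO", "CCO", "C(F)(F)F"
)

DEFAULT_TOXICOPHORE_SMARTS <- "a[N+](=O)[O-]"
DEFAULT_TOXICOPHORE_GROUP <- "[N+](=O)[O-]"

fill_template <- function(tpl, A = "", B = "", C = "") {
  s <- tpl
  s <- gsub("{A}", A, s, fixed = TRUE)
  s <- gsub("{B}", B, s, fixed = TRUE)
  s <- gsub("{C}", C, s, fixed = TRUE)
  gsub("()", "", s, fixed = TRUE)
}

# batched SMARTS matching through the obabel filter (-s); returns logical
ob_matches_smarts <- function(smiles, smarts) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, paste0("m", seq_len(n))), infile)
  out <- suppressWarnings(system2(
    OB_BIN, c(infile, "-osmi", "-e", paste0("-s", shQuote(smarts))),
    stdout = TRUE, stderr = FALSE
  ))
  hit <- rep(FALSE, n)
  idx <- as.integer(stringr::str_match(out, "\\sm(\\d+)\\s*$")[, 2])
  hit[idx[!is.na(idx)]] <- TRUE
  hit
}

#' Configuration for the synthetic benchmark generator
#'
#' @param n_active,n_inactive Exact class counts in the generated library.
#' @param toxicophore SMARTS pattern that defines structural activity.
#' @param toxicophore_group Attachment fragment planted on active scaffolds;
#'   must produce molecules matching `toxicophore`.
#' @param assay_specs Data frame with columns `assay`, `hit_prob_active`,
#'   `hit_prob_inactive`, `missing_rate` (one row per assay).
#' @param label_noise Fraction of compounds whose activity label is flipped
#'   relative to the structural ground truth.
#' @param seed Integer seed; the full generation is deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_active, n_inactive,
                             toxicophore = DEFAULT_TOXICOPHORE_SMARTS,
                             toxicophore_group = DEFAULT_TOXICOPHORE_GROUP,
                             assay_specs = default_assay_specs(3),
                             label_noise = 0, seed = 1L) {
  stopifnot(n_active + n_inactive >= 10, label_noise >= 0, label_noise <= 1)
  stopifnot(all(c("assay", "hit_prob_active", "hit_prob_inactive",
                  "missing_rate") %in% names(assay_specs)))
  stopifnot(all(assay_specs$hit_prob_active >= 0 & assay_specs$hit_prob_active <= 1),
            all(assay_specs$missing_rate >= 0 & assay_specs$missing_rate <= 1))
  structure(list(
    n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
    toxicophore = toxicophore, toxicophore_group = toxicophore_group,
    assay_specs = tibble::as_tibble(assay_specs),
    label_noise = label_noise, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default per-assay noise specification
#'
#' @param n_assays Number of assays.
#' @param hit_prob_active,hit_prob_inactive,missing_rate Shared per-assay
#'   class-conditional hit probabilities and missing rate.
#' @return Tibble usable as `assay_specs` in [synthetic_config()].
#' @export
default_assay_specs <- function(n_assays, hit_prob_active = 0.4,
                                hit_prob_inactive = 0.02, missing_rate = 0.1) {
  tibble::tibble(
    assay = paste0("assay_", seq_len(n_assays)),
    hit_prob_active = hit_prob_active,
    hit_prob_inactive = hit_prob_inactive,
    missing_rate = missing_rate
  )
}

#' Generate a synthetic compound library with planted ground truth
#'
#' Molecules are assembled from a fragment grammar (aromatic and aliphatic
#' scaffolds decorated from a small substituent set). Active compounds carry
#' the toxicophore substructure; inactives never do (before `label_noise`).
#' All SMILES are canonical parents (curation-stable) and class counts are
#' exact by construction.
#'
#' @param cfg A [synthetic_config()].
#' @return Tibble: `canonical_smiles`, `active` (label after noise),
#'   `toxicophore_present` (structural truth).
#' @export
generate_library <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    actives <- sample_structures(cfg$n_active, active = TRUE,
                                 group = cfg$toxicophore_group)
    inactives <- sample_structures(cfg$n_inactive, active = FALSE,
                                   group = cfg$toxicophore_group,
                                   avoid = actives)
    if (cfg$n_active > 0) {
      match_ok <- ob_matches_smarts(actives[seq_len(min(20, length(actives)))],
                                    cfg$toxicophore)
      if (!all(match_ok)) {
        stop("generate_library: toxicophore_group does not realize the ",
             "toxicophore pattern '", cfg$toxicophore, "'")
      }
    }
    lib <- tibble::tibble(
      canonical_smiles = c(actives, inactives),
      toxicophore_present = rep(c(TRUE, FALSE), c(length(actives), length(inactives)))
    )
    lib <- lib[sample.int(nrow(lib)), , drop = FALSE]
    lib$active <- lib$toxicophore_present
    n_flip <- round(cfg$label_noise * nrow(lib))
    if (n_flip > 0) {
      flip <- sample.int(nrow(lib), n_flip)
      lib$active[flip] <- !lib$active[flip]
    }
    lib
  })
}

# draw `n` distinct canonical structures; actives put the toxicophore group
# in slot A of an aromatic template
sample_structures <- function(n, active, group, avoid = character(0)) {
  if (n == 0L) return(character(0))
  got <- character(0)
  tries <- 0L
  while (length(got) < n && tries < 60L) {
    tries <- tries + 1L
    m <- max(200L, 2L * (n - length(got)))
    raw <- if (active) {
      tpl <- sample(AROMATIC_TEMPLATES, m, replace = TRUE)
      fill_template_vec(tpl, A = group,
                        B = sample(DECORATIONS, m, replace = TRUE),
                        C = sample(DECORATIONS, m, replace = TRUE))
    } else {
      tpl <- sample(c(AROMATIC_TEMPLATES, ALIPHATIC_TEMPLATES), m, replace = TRUE)
      fill_template_vec(tpl, A = sample(DECORATIONS, m, replace = TRUE),
                        B = sample(DECORATIONS, m, replace = TRUE),
                        C = sample(DECORATIONS, m, replace = TRUE))
    }
    can <- ob_canonical_smiles(raw, strip_stereo = TRUE)
    can <- can[!is.na(can)]
    got <- setdiff(unique(c(got, can)), avoid)
  }
  if (length(got) < n) {
    stop("sample_structures: grammar exhausted at ", length(got),
         " distinct structures (needed ", n, ")")
  }
  got[seq_len(n)]
}

fill_template_vec <- function(tpl, A, B, C) {
  A <- rep_len(A, length(tpl)); B <- rep_len(B, length(tpl)); C <- rep_len(C, length(tpl))
  vapply(seq_along(tpl), function(i) fill_template(tpl[i], A[i], B[i], C[i]),
         character(1))
}

#' Generate an assay hit-call matrix for a compound library
#'
#' Each call is drawn independently: hit probability conditional on the
#' compound's activity label, then missingness applied independently.
#'
#' @param library Tibble from [generate_library()] (needs `canonical_smiles`
#'   and `active`).
#' @param cfg A [synthetic_config()]; uses its `assay_specs` and `seed`.
#' @return Wide tibble: `compound` plus one column per assay with values
#'   `"active"`, `"inactive"`, or `NA` (missing).
#' @export
generate_assay_matrix <- function(library, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  spec <- cfg$assay_specs
  stopifnot(nrow(spec) >= 1)
  withr::with_seed(cfg$seed + 1L, {
    n <- nrow(library)
    out <- tibble::tibble(compound = library$canonical_smiles)
    for (j in seq_len(nrow(spec))) {
      p <- ifelse(library$active, spec$hit_prob_active[j], spec$hit_prob_inactive[j])
      call <- ifelse(stats::runif(n) < p, "active", "inactive")
      call[stats::runif(n) < spec$missing_rate[j]] <- NA_character_
      out[[spec$assay[j]]] <- call
    }
    out
  })
}

BENCHMARK_PRESETS <- list(
  mie1_like = list(n_active = 184L, n_inactive = 48L, n_assays = 6L, endpoint = "MIE1"),
  ke1_like = list(n_active = 191L, n_inactive = 445L, n_assays = 7L, endpoint = "KE1"),
  ke2_like = list(n_active = 1147L, n_inactive = 3857L, n_assays = 12L, endpoint = "KE2")
)

#' Generate a preset endpoint benchmark
#'
#' Presets mirror the sizes and class imbalances of the three AOP endpoint
#' datasets (MIE1-like: 232 compounds, 79% active; KE1-like: 636, 30%;
#' KE2-like: 5004, 23%) with exact class counts. The endpoint dataset is
#' built from the structural ground truth (plus `label_noise`); the assay
#' matrix carries the configured per-assay noise for exercising the
#' labelling stage.
#'
#' @param preset One of `"mie1_like"`, `"ke1_like"`, `"ke2_like"`.
#' @param seed Integer seed.
#' @param label_noise Fraction of flipped labels (default 0).
#' @param assay_specs Optional override of the per-assay noise table.
#' @param dir Optional directory: writes `compounds.csv`, `hitcalls.csv`,
#'   `endpoint.yaml` in the dialects the readers consume.
#' @return List: `library`, `calls`, `dataset` (endpoint tibble), `summary`.
#' @export
generate_benchmark <- function(preset = names(BENCHMARK_PRESETS), seed = 1L,
                               label_noise = 0, assay_specs = NULL, dir = NULL) {
  preset <- match.arg(preset)
  p <- BENCHMARK_PRESETS[[preset]]
  cfg <- synthetic_config(
    n_active = p$n_active, n_inactive = p$n_inactive,
    assay_specs = assay_specs %||% default_assay_specs(p$n_assays),
    label_noise = label_noise, seed = seed
  )
  library <- generate_library(cfg)
  calls <- generate_assay_matrix(library, cfg)
  ds <- tibble::tibble(compound = library$canonical_smiles, active = library$active)
  attr(ds, "endpoint") <- p$endpoint
  attr(ds, "n_assays_used") <- p$n_assays
  class(ds) <- c("endpoint_dataset", class(ds))
  res <- list(library = library, calls = calls, dataset = ds,
              summary = dataset_summary(ds), config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(id = paste0("cmp", seq_len(nrow(library))),
                 smiles = library$canonical_smiles,
                 active = library$active,
                 toxicophore_present = library$toxicophore_present),
      file.path(dir, "compounds.csv"), row.names = FALSE)
    utils::write.csv(calls, file.path(dir, "hitcalls.csv"), row.names = FALSE, na = "")
    yaml::write_yaml(
      list(endpoints = stats::setNames(list(cfg$assay_specs$assay), p$endpoint)),
      file.path(dir, "endpoint.yaml")
    )
  }
  res
}

#' Test molecules for the presence of a toxicophore substructure
#'
#' @param smiles Character vector of SMILES.
#' @param smarts SMARTS pattern (default: aromatic nitro group).
#' @return Logical vector.
#' @export
has_toxicophore <- function(smiles, smarts = DEFAULT_TOXICOPHORE_SMARTS) {
  ob_matches_smarts(smiles, smarts)
}
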