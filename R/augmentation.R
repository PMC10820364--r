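#' Enumerate alternative SMILES renderings of a molecule
#'
#' Generates distinct non-canonical SMILES strings for the same molecule by
#' random atom-rank permutation before writing. Every output canonicalizes
#' back to the input; fewer than `n_variants` strings are returned when the
#' molecule admits fewer distinct renderings.
#'
#' @param canonical_smiles A single valid canonical SMILES string.
#' @param n_variants Maximum number of distinct renderings to return.
#' @param seed Integer seed (the enumeration is deterministic given it).
#' @param max_tries Permutation attempts before giving up on new variants.
#' @return Character vector of distinct SMILES (may include the canonical
#'   form itself).
#' @export
enumerate_smiles <- function(canonical_smiles, n_variants, seed = 1L,
                             max_tries = 10L * n_variants) {
  stopifnot(length(canonical_smiles) == 1L, n_variants >= 1)
  mol <- parse_molecules(canonical_smiles)[[1]]
  if (is.null(mol)) stop("enumerate_smiles: invalid SMILES '", canonical_smiles, "'")
  n <- nrow(mol$atoms)
  if (n <= 1L) return(canonical_smiles)
  withr::with_seed(seed, {
    seen <- character(0)
    tries <- 0L
    while (length(seen) < n_variants && tries < max_tries) {
      tries <- tries + 1L
      smi <- tryCatch(molblock_smiles(mol, sample.int(n)), error = function(e) NA)
      if (!is.na(smi) && nzchar(smi)) seen <- union(seen, smi)
    }
    seen
  })
}

#' Augment a training set by SMILES enumeration
#'
#' Each training compound contributes its canonical SMILES plus up to
#' `factor - 1` enumerated variants; variants inherit the parent's activity
#' label, so the class ratio among parents is preserved. Refuses to run on
#' test/validation partitions (leakage guard).
#'
#' @param train Tibble with `compound` (canonical SMILES) and `active`
#'   columns, as produced by [stratified_split()]; its `partition` attribute
#'   (when present) must be `"train"`.
#' @param factor Target multiplication factor (default 10).
#' @param seed Integer seed.
#' @return An `augmented_set` tibble: `smiles`, `parent`, `active`; attribute
#'   `provenance` records seed and factor.
#' @export
augment_training_set <- function(train, factor = 10, seed = 1L) {
  stopifnot(is.data.frame(train), factor >= 1)
  part <- attr(train, "partition")
  if (!is.null(part) && !identical(part, "train")) {
    stop("augment_training_set: refusing to augment a '", part,
         "' partition; augmentation is train-only")
  }
  smi_col <- intersect(c("compound", "canonical_smiles", "smiles"), names(train))[1]
  stopifnot(!is.na(smi_col), "active" %in% names(train))
  parents <- as.character(train[[smi_col]])
  labels <- train$active
  entries <- withr::with_seed(seed, {
    purrr::map(seq_along(parents), function(i) {
      variants <- if (factor > 1) {
        setdiff(
          enumerate_smiles(parents[i], n_variants = factor - 1,
                           seed = sample.int(.Machine$integer.max, 1)),
          parents[i]
        )
      } else character(0)
      tibble::tibble(
        smiles = c(parents[i], variants),
        parent = parents[i],
        active = labels[i]
      )
    })
  })
  out <- dplyr::bind_rows(entries)
  attr(out, "provenance") <- list(seed = seed, factor = factor)
  attr(out, "partition") <- "train"
  class(out) <- c("augmented_set", class(out))
  out
}
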