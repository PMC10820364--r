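#' Canonicalize SMILES strings
#'
#' Converts raw SMILES to the toolkit-canonical form (OpenBabel canonical
#' SMILES). Canonicalization is idempotent and maps chemically equal inputs
#' to the same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strip_stereo Drop tetrahedral and double-bond stereo descriptors
#'   before writing the canonical form.
#' @return Character vector of canonical SMILES, `NA` where the input could
#'   not be parsed.
#' @examples
#' canonicalize_smiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonicalize_smiles <- function(smiles, strip_stereo = FALSE) {
  stopifnot(is.character(smiles))
  bad <- is.na(smiles) | !nzchar(trimws(smiles))
  if (any(bad & !is.na(smiles))) {
    stop("canonicalize_smiles: empty SMILES string at position ",
         which(bad & !is.na(smiles))[1])
  }
  ob_canonical_smiles(smiles, strip_stereo = strip_stereo)
}

#' Reduce a structure to its canonical parent
#'
#' Keeps the largest disconnected fragment (salt/solvent stripping), removes
#' stereochemistry, and re-canonicalizes. Fragment size ties are broken by
#' heavy-atom count, then molecular weight, then lexicographic canonical
#' SMILES, so the result is order-independent.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical parent SMILES (`NA` on failure).
#' @examples
#' strip_to_parent("[Na+].CC(=O)[O-]")
#' @export
strip_to_parent <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  frag_list <- strsplit(ifelse(is.na(smiles), "", smiles), ".", fixed = TRUE)
  frag_df <- tibble::tibble(
    rec = rep(seq_len(n), lengths(frag_list)),
    frag = unlist(frag_list)
  )
  frag_df <- frag_df[nzchar(frag_df$frag), , drop = FALSE]
  out <- rep(NA_character_, n)
  if (nrow(frag_df) == 0L) return(out)
  frag_df$can <- ob_canonical_smiles(frag_df$frag, strip_stereo = TRUE)
  frag_df <- frag_df[!is.na(frag_df$can), , drop = FALSE]
  if (nrow(frag_df) == 0L) return(out)

  counts <- table(frag_df$rec)
  single <- as.integer(names(counts)[counts == 1L])
  out[single] <- frag_df$can[frag_df$rec %in% single]

  multi <- as.integer(names(counts)[counts > 1L])
  if (length(multi)) {
    sub <- frag_df[frag_df$rec %in% multi, , drop = FALSE]
    info <- fragment_size_info(sub$can)
    sub$heavy_atoms <- info$heavy_atoms
    sub$mw <- info$mw
    best <- sub |>
      dplyr::group_by(.data$rec) |>
      dplyr::arrange(-.data$heavy_atoms, -.data$mw, .data$can, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    out[best$rec] <- best$can
  }
  out
}

fragment_size_info <- function(frags) {
  mols <- parse_molecules(frags)
  tibble::tibble(
    smiles = frags,
    heavy_atoms = vapply(mols, function(m) nrow(m$atoms), integer(1)),
    mw = vapply(mols, function(m) {
      sum(ATOMIC_MASS[m$atoms$symbol] + m$atoms$n_hydrogens * ATOMIC_MASS[["H"]])
    }, numeric(1))
  )
}

# element whitelist used by the "inconsistency" screen; configurable
DEFAULT_ELEMENT_WHITELIST <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "H")

#' Curate a raw compound table
#'
#' Takes identifier + SMILES records and produces a duplicate-free table of
#' canonical parent structures: canonicalization, salt stripping, stereo
#' removal, an element-whitelist screen, and merging of records whose parent
#' structures coincide. Records that fail any step land in the rejection log
#' (attribute `"rejections"`, also returned by [curation_rejections()]), never
#' silently dropped.
#'
#' @param records Data frame with identifier and SMILES columns.
#' @param id_col,smiles_col Column names (defaults `"id"`, `"smiles"`).
#' @param element_whitelist Allowed element symbols; structures containing
#'   anything else are rejected as likely encoding errors.
#' @return A tibble with one row per unique parent structure: `canonical_smiles`,
#'   `source_ids` (list column), `flags` (list column of curation annotations).
#' @examples
#' curate_compounds(data.frame(id = c("a", "b"), smiles = c("OCC", "CCO")))
#' @export
curate_compounds <- function(records, id_col = "id", smiles_col = "smiles",
                             element_whitelist = DEFAULT_ELEMENT_WHITELIST) {
  stopifnot(is.data.frame(records))
  if (!all(c(id_col, smiles_col) %in% names(records))) {
    stop("curate_compounds: missing column(s) ",
         paste(setdiff(c(id_col, smiles_col), names(records)), collapse = ", "))
  }
  ids <- as.character(records[[id_col]])
  raw <- as.character(records[[smiles_col]])
  n <- length(raw)
  reject <- tibble::tibble(id = character(), smiles = character(), reason = character())
  if (n == 0L) {
    out <- tibble::tibble(canonical_smiles = character(),
                          source_ids = list(), flags = list())
    attr(out, "rejections") <- reject
    return(out)
  }

  empty <- is.na(raw) | !nzchar(trimws(raw))
  can0 <- rep(NA_character_, n)
  can0[!empty] <- ob_canonical_smiles(raw[!empty])
  parse_fail <- !empty & is.na(can0)

  parent <- rep(NA_character_, n)
  parent[!is.na(can0)] <- strip_to_parent(can0[!is.na(can0)])
  strip_fail <- !is.na(can0) & is.na(parent)

  elem_ok <- rep(NA, n)
  ok_idx <- which(!is.na(parent))
  if (length(ok_idx)) {
    elem_ok[ok_idx] <- vapply(parent[ok_idx], function(s) {
      syms <- smiles_element_symbols(s)
      all(syms %in% element_whitelist)
    }, logical(1))
  }

  add_reject <- function(mask, reason) {
    if (any(mask)) {
      reject <<- dplyr::bind_rows(reject, tibble::tibble(
        id = ids[mask], smiles = raw[mask], reason = reason))
    }
  }
  add_reject(empty, "empty_smiles")
  add_reject(parse_fail, "parse_failure")
  add_reject(strip_fail, "strip_failure")
  add_reject(!is.na(elem_ok) & !elem_ok, "element_outside_whitelist")

  keep <- !is.na(parent) & !is.na(elem_ok) & elem_ok
  per_rec <- tibble::tibble(
    id = ids[keep],
    canonical_smiles = parent[keep],
    salt_stripped = grepl(".", can0[keep], fixed = TRUE),
    stereo_removed = grepl("[@/\\\\]", can0[keep])
  )
  out <- per_rec |>
    dplyr::group_by(.data$canonical_smiles) |>
    dplyr::summarise(
      source_ids = list(unique(.data$id)),
      flags = list(curation_flags(.data$salt_stripped, .data$stereo_removed,
                                  dplyr::n() > 1L)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$canonical_smiles)
  attr(out, "rejections") <- reject
  out
}

curation_flags <- function(salt, stereo, merged) {
  f <- character(0)
  if (any(salt)) f <- c(f, "salt_stripped")
  if (any(stereo)) f <- c(f, "stereo_removed")
  if (merged) f <- c(f, "merged_duplicate")
  f
}

#' Rejection log of a curated table
#'
#' @param curated Result of [curate_compounds()].
#' @return Tibble with columns `id`, `smiles`, `reason`.
#' @export
curation_rejections <- function(curated) {
  rej <- attr(curated, "rejections")
  if (is.null(rej)) tibble::tibble(id = character(), smiles = character(),
                                   reason = character()) else rej
}

# element symbols occurring in a SMILES string (two-letter organics first;
# aromatic lowercase atoms, bracketed or not, map to their uppercase element)
smiles_element_symbols <- function(smi) {
  s <- smi
  brackets <- stringr::str_match_all(s, "\\[[0-9]*([A-Za-z][a-z]?)")[[1]][, 2]
  # bracket captures: "nH" / "n" -> N (aromatic); "Cl" stays; "se" -> Se
  brackets <- vapply(brackets, function(tok) {
    if (grepl("^[A-Z]", tok)) {
      if (grepl("^[A-Z][a-z]$", tok) &&
          substr(tok, 2, 2) %in% c("H")) substr(tok, 1, 1) else tok
    } else if (tok %in% c("se", "as", "te")) {
      paste0(toupper(substr(tok, 1, 1)), substr(tok, 2, 2))
    } else {
      toupper(substr(tok, 1, 1))
    }
  }, character(1), USE.NAMES = FALSE)
  s <- gsub("\\[[^]]*\\]", "", s)
  twos <- stringr::str_extract_all(s, "Cl|Br|Si")[[1]]
  s <- gsub("Cl|Br|Si", "", s)
  letters_left <- stringr::str_extract_all(s, "[A-Za-z]")[[1]]
  syms <- c(brackets, twos, toupper(letters_left))
  unique(syms[nzchar(syms)])
}

#' Read a compound table from CSV or SDF
#'
#' @param path File path; `.sdf` files are read with ChemmineR, anything else
#'   as CSV.
#' @param id_col,smiles_col CSV column names.
#' @return Tibble with `id` and `smiles` columns.
#' @export
read_compounds <- function(path, id_col = "id", smiles_col = "smiles") {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfset <- ChemmineR::read.SDFset(path)
    smi <- suppressWarnings(ChemmineR::sdf2smiles(sdfset))
    return(tibble::tibble(id = ChemmineR::sdfid(sdfset),
                          smiles = as.character(smi)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tibble::tibble(id = as.character(df[[id_col]]), smiles = df[[smiles_col]])
}

#' Write a curated table (and its rejection log) to disk
#'
#' @param curated Result of [curate_compounds()].
#' @param path Output CSV path; `source_ids`/`flags` are `;`-joined.
#' @param log_path Optional TSV path for the rejection log.
#' @export
write_curated <- function(curated, path, log_path = NULL) {
  flat <- dplyr::mutate(
    curated,
    source_ids = vapply(.data$source_ids, paste, character(1), collapse = ";"),
    flags = vapply(.data$flags, paste, character(1), collapse = ";")
  )
  utils::write.csv(flat, path, row.names = FALSE)
  if (!is.null(log_path)) {
    utils::write.table(curation_rejections(curated), log_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
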