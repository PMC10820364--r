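# Low-level chemistry backend: OpenBabel (obabel CLI + ChemmineOB/ChemmineR).
# All higher modules go through these wrappers so the toolkit is swappable.

OB_BIN <- "obabel"

ob_available <- function() nzchar(Sys.which(OB_BIN))

# Run obabel over a batch of SMILES, one per line, each tagged with a title
# "m<i>" so per-record failures can be mapped back (failed records are simply
# absent from the output). Returns a character vector aligned to `smiles`,
# NA where conversion failed.
ob_smiles_batch <- function(smiles, out_format = "can", extra = character()) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", trimws(smiles))
  res <- rep(NA_character_, n)
  if (!any(ok)) return(res)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(trimws(smiles[ok]), paste0("m", which(ok))), infile)
  out <- suppressWarnings(system2(
    OB_BIN, c(infile, paste0("-o", out_format), "-e", extra),
    stdout = TRUE, stderr = FALSE
  ))
  out <- out[nzchar(out)]
  if (length(out) == 0L) return(res)
  parts <- stringr::str_match(out, "^(\\S+)\\s+m(\\d+)\\s*$")
  hit <- !is.na(parts[, 1])
  idx <- as.integer(parts[hit, 3])
  res[idx] <- parts[hit, 2]
  res
}

# Canonical SMILES; optionally with stereochemistry descriptors dropped
# (obabel output option -xi). NA for unparsable input.
ob_canonical_smiles <- function(smiles, strip_stereo = FALSE) {
  extra <- if (strip_stereo) "-xi" else character()
  ob_smiles_batch(smiles, out_format = "can", extra = extra)
}

# ---- fingerprints ------------------------------------------------------------

FP_NBITS <- c(
  MACCS = 256L, FP3 = 64L, FP4 = 512L,
  ECFP0 = 4096L, ECFP2 = 4096L, ECFP4 = 4096L,
  ECFP6 = 4096L, ECFP8 = 4096L, ECFP10 = 4096L
)

# Parse one 32-bit hex word into its 32 bits without integer overflow
# (strtoi() cannot take "ffffffff"); words are split into 16-bit halves.
hex_word_bits <- function(words) {
  hi <- strtoi(substr(words, 1L, 4L), 16L)
  lo <- strtoi(substr(words, 5L, 8L), 16L)
  bits <- matrix(FALSE, length(words), 32L)
  for (b in 0:15) {
    bits[, b + 1L] <- bitwAnd(lo, bitwShiftL(1L, b)) != 0L
    bits[, b + 17L] <- bitwAnd(hi, bitwShiftL(1L, b)) != 0L
  }
  bits
}

# Batched fingerprints through `obabel -ofpt -xh`: ~1000 molecules/s versus
# ~8/s for per-molecule ChemmineOB::fingerprint_OB calls. The hex layout
# (most-significant 32-bit word first) was cross-checked against
# fingerprint_OB bit indices. Returns an n x nbits 0/1 integer matrix with
# NA rows where the molecule failed to parse.
ob_fingerprint_matrix <- function(smiles, type = "ECFP4") {
  type <- match.arg(type, names(FP_NBITS))
  nbits <- FP_NBITS[[type]]
  n <- length(smiles)
  res <- matrix(NA_integer_, n, nbits)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles[ok], paste0("m", which(ok))), infile)
  out <- suppressWarnings(system2(
    OB_BIN, c(infile, "-ofpt", paste0("-xf", type), "-xh", "-e"),
    stdout = TRUE, stderr = FALSE
  ))
  hdr <- grep("^>", out)
  if (length(hdr) == 0L) return(res)
  ends <- c(hdr[-1] - 1L, length(out))
  for (k in seq_along(hdr)) {
    title <- stringr::str_match(out[hdr[k]], "^>\\s*m(\\d+)")[, 2]
    if (is.na(title)) next
    block <- out[hdr[k]:ends[k]]
    hexlines <- grep("^[0-9a-f]{8}( [0-9a-f]{8})* *$", block, value = TRUE)
    words <- unlist(strsplit(trimws(hexlines), "\\s+"))
    if (length(words) * 32L < nbits) next
    bits <- hex_word_bits(words)           # row w = word w (MSW first)
    flat <- as.vector(t(bits[rev(seq_len(nrow(bits))), , drop = FALSE]))
    res[as.integer(title), ] <- as.integer(flat[seq_len(nbits)])
  }
  res
}

# ---- molecule tables ---------------------------------------------------------

STANDARD_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, H = 1
)

# MDL charge codes in atom-block field 5 (ChemmineR atomblock column "C5").
MDL_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                `5` = -1L, `6` = -2L, `7` = -3L)

ELECTRONEGATIVITY <- c(
  B = 2.04, C = 2.55, N = 3.04, O = 3.44, F = 3.98, Si = 1.90, P = 2.19,
  S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66, H = 2.20
)
ATOMIC_MASS <- c(
  B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998, Si = 28.086,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904, H = 1.008
)
ATOMIC_NUMBER <- c(
  B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Br = 35L, I = 53L, H = 1L
)
# First ionization energies, eV (for autocorrelation weights).
IONIZATION_EV <- c(
  B = 8.30, C = 11.26, N = 14.53, O = 13.62, F = 17.42, Si = 8.15,
  P = 10.49, S = 10.36, Cl = 12.97, Br = 11.81, I = 10.45, H = 13.60
)

# Parse a vector of (valid, canonical) SMILES into per-molecule atom/bond
# tables. The V2000 connection table written by OpenBabel is parsed directly
# (atom order there follows the SMILES atom order, which also carries the
# aromaticity of each atom via its lowercase rendering). Implicit hydrogens
# and valences are derived from standard valences adjusted by formal charge.
# Returns a list of list(atoms = tibble, bonds = tibble); NULL entries where
# parsing failed.
parse_molecules <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (!length(ok)) return(out)
  txt <- ChemmineOB::convertFormat(
    "SMI", "SDF",
    paste(paste(smiles[ok], paste0("m", ok)), collapse = "\n")
  )
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]
    while (length(lines) && !nzchar(lines[1])) lines <- lines[-1]
    if (length(lines) < 4) next
    i <- suppressWarnings(as.integer(sub("^m", "", trimws(lines[1]))))
    if (is.na(i)) next
    tab <- tryCatch(parse_v2000(lines, smiles[i]), error = function(e) NULL)
    out[[i]] <- tab
  }
  out
}

# atom tokens of a SMILES string in order, with per-atom aromatic flags
smiles_atom_tokens <- function(smi) {
  pat <- "\\[[^]]*\\]|Cl|Br|Si|[BCNOPSFI]|[bcnops]"
  toks <- stringr::str_extract_all(smi, pat)[[1]]
  arom <- vapply(toks, function(tk) {
    if (startsWith(tk, "[")) {
      ch <- stringr::str_match(tk, "^\\[[0-9]*([A-Za-z])")[, 2]
      !is.na(ch) && ch %in% c("b", "c", "n", "o", "p", "s")
    } else {
      substr(tk, 1, 1) %in% c("b", "c", "n", "o", "p", "s")
    }
  }, logical(1), USE.NAMES = FALSE)
  arom
}

parse_v2000 <- function(lines, smi) {
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  m <- as.integer(substr(counts, 4, 6))
  stopifnot(!is.na(n), n >= 1)
  atom_lines <- lines[5:(4 + n)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge_code <- trimws(substr(atom_lines, 37, 39))
  charge <- unname(MDL_CHARGE[charge_code])
  charge[is.na(charge)] <- 0L
  bonds <- if (m > 0) {
    bl <- lines[(5 + n):(4 + n + m)]
    tibble::tibble(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, n)   # property block supersedes legacy codes
    for (cl in chg_lines) {
      flds <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
      k <- flds[1]
      for (j in seq_len(k)) {
        charge[flds[2 * j]] <- flds[2 * j + 1]
      }
    }
  }
  arom_atoms <- smiles_atom_tokens(smi)
  if (length(arom_atoms) != n) arom_atoms <- rep(FALSE, n)
  mol_tables(symbol, charge, bonds, arom_atoms)
}

mol_tables <- function(symbol, charge, bonds, arom_atoms) {
  n <- length(symbol)
  bond_arom <- arom_atoms[bonds$a1] & arom_atoms[bonds$a2] &
    in_same_ring(bonds, n)

  # bond order sum per atom; aromatic ring bonds counted from the kekulized
  # orders OpenBabel writes, so sums stay integral
  deg_order <- rep(0, n)
  if (nrow(bonds)) {
    deg_order <- deg_order +
      tapply_sum(bonds$a1, bonds$order, n) + tapply_sum(bonds$a2, bonds$order, n)
  }
  base_val <- unname(STANDARD_VALENCE[symbol])
  base_val[is.na(base_val)] <- 0
  # charge-adjusted bonding capacity: N+ binds 4, O- binds 1, etc.
  cap <- base_val + ifelse(symbol %in% c("N", "O", "P", "S", "B"), charge, 0)
  # hypervalent S/P: lift capacity to the next standard valence when exceeded
  cap <- ifelse(symbol == "S" & deg_order > cap, ifelse(deg_order > 4, 6, 4), cap)
  cap <- ifelse(symbol == "P" & deg_order > cap, 5, cap)
  n_h <- pmax(0, round(cap - deg_order))

  hyb <- atom_hybridization(symbol, bonds, arom_atoms, n)

  atoms <- tibble::tibble(
    symbol = symbol,
    atomic_number = unname(ATOMIC_NUMBER[symbol]),
    charge = charge,
    aromatic = arom_atoms,
    degree = atom_degree(bonds, n),
    valence = deg_order + n_h,
    n_hydrogens = n_h,
    hybridization = hyb
  )
  bonds$aromatic <- if (nrow(bonds)) bond_arom else logical(0)
  bonds$conjugated <- bond_conjugated(bonds, atoms)
  list(atoms = atoms, bonds = bonds)
}

tapply_sum <- function(idx, val, n) {
  out <- rep(0, n)
  s <- tapply(val, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

atom_degree <- function(bonds, n) {
  d <- rep(0L, n)
  if (nrow(bonds)) {
    t1 <- table(factor(bonds$a1, levels = seq_len(n)))
    t2 <- table(factor(bonds$a2, levels = seq_len(n)))
    d <- as.integer(t1 + t2)
  }
  d
}

in_same_ring <- function(bonds, n) {
  # aromatic flag is only granted to actual ring bonds; cheap cycle check via
  # "bond lies on a cycle" = endpoints still connected after bond removal
  if (!nrow(bonds)) return(logical(0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (j in seq_len(nrow(bonds))) {
    adj[[bonds$a1[j]]] <- c(adj[[bonds$a1[j]]], j)
    adj[[bonds$a2[j]]] <- c(adj[[bonds$a2[j]]], j)
  }
  vapply(seq_len(nrow(bonds)), function(j) {
    from <- bonds$a1[j]; to <- bonds$a2[j]
    seen <- rep(FALSE, n); seen[from] <- TRUE; queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == j) next
        w <- if (bonds$a1[e] == v) bonds$a2[e] else bonds$a1[e]
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE; queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

atom_hybridization <- function(symbol, bonds, arom, n) {
  # sp3 = 3, sp2 = 2, sp = 1 (code used as a node feature)
  max_order <- rep(1, n)
  if (nrow(bonds)) {
    for (j in seq_len(nrow(bonds))) {
      max_order[bonds$a1[j]] <- max(max_order[bonds$a1[j]], bonds$order[j])
      max_order[bonds$a2[j]] <- max(max_order[bonds$a2[j]], bonds$order[j])
    }
  }
  n_triple <- rep(0L, n)
  n_double <- rep(0L, n)
  if (nrow(bonds)) {
    for (j in seq_len(nrow(bonds))) {
      if (bonds$order[j] == 3) {
        n_triple[bonds$a1[j]] <- n_triple[bonds$a1[j]] + 1L
        n_triple[bonds$a2[j]] <- n_triple[bonds$a2[j]] + 1L
      } else if (bonds$order[j] == 2) {
        n_double[bonds$a1[j]] <- n_double[bonds$a1[j]] + 1L
        n_double[bonds$a2[j]] <- n_double[bonds$a2[j]] + 1L
      }
    }
  }
  code <- ifelse(n_triple > 0 | n_double >= 2, 1L, ifelse(n_double == 1 | arom, 2L, 3L))
  code
}

bond_conjugated <- function(bonds, atoms) {
  if (!nrow(bonds)) return(logical(0))
  unsat <- atoms$hybridization <= 2L   # sp2/sp atoms carry pi systems
  unsat[atoms$aromatic] <- TRUE
  bonds_arom <- if ("aromatic" %in% names(bonds)) bonds$aromatic else FALSE
  (unsat[bonds$a1] & unsat[bonds$a2]) | bonds_arom
}

# Rewrite a molecule's SMILES with atoms in a given order: permute the MDL
# atom block, remap bond indices, and let the (non-canonical) SMILES writer
# follow the new atom ranks. This is the enumeration primitive used for
# augmentation.
smiles_with_atom_order <- function(smiles, perm = NULL, seed = NULL) {
  mol <- parse_molecules(smiles)[[1]]
  n <- nrow(mol$atoms)
  if (n <= 1L) return(smiles)
  if (is.null(perm)) {
    if (!is.null(seed)) withr::local_seed(seed)
    perm <- sample.int(n)
  }
  molblock_smiles(mol, perm)
}

molblock_smiles <- function(mol, perm) {
  n <- nrow(mol$atoms)
  inv <- order(perm)
  sym <- mol$atoms$symbol[perm]
  chg <- mol$atoms$charge[perm]
  bonds <- mol$bonds
  lines <- c("mol", "  aopqsar", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)))
  chg_code <- vapply(chg, function(c) {
    names(MDL_CHARGE)[match(c, MDL_CHARGE)][1]
  }, character(1))
  chg_code[is.na(chg_code)] <- "0"
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0%3s  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, sym[i], chg_code[i]
    ))
  }
  if (nrow(bonds)) {
    for (j in seq_len(nrow(bonds))) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                inv[bonds$a1[j]], inv[bonds$a2[j]], bonds$order[j]))
    }
  }
  lines <- c(lines, "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "SMI", paste(lines, collapse = "\n"))
  out <- strsplit(out, "[\t\n ]")[[1]]
  out[nzchar(out)][1]
}
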