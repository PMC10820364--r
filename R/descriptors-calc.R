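# 1-2D molecular descriptor calculator: constitutional counts, topological
# indices, Moreau-Broto/Moran/Geary autocorrelations over atomic weights,
# atom-type counts, and OpenBabel physico-chemical properties. Width is fixed
# for every molecule; cells that cannot be computed (degenerate graphs) are NA
# and left to feature preprocessing.

AC_LAGS <- 1:6
AC_WEIGHTS <- c("mass", "en", "ion", "deg")

descriptor_names <- function() {
  consts <- c(
    "nAtoms", "nBonds", "nH", "MW", "nRings", "nAromAtoms", "fAromAtoms",
    "nAromBonds", "nC", "nN", "nO", "nS", "nP", "nF", "nCl", "nBr", "nI",
    "nB", "nSi", "nHet", "fHet", "nHalogen", "nPosCharge", "nNegCharge",
    "nSp", "nSp2", "nSp3", "nRotBonds", "nHBDon", "nHBAcc",
    "nSingleBonds", "nDoubleBonds", "nTripleBonds", "nConjBonds"
  )
  topo <- c(
    "Wiener", "MeanDist", "Diameter", "Radius", "Harary", "Zagreb1",
    "Zagreb2", "Randic", "BalabanJ", "Platt", "P2", "P3",
    "Kappa1", "Kappa2", "GraphDensity", "MeanDeg", "MaxDeg", "TotalEN",
    "MeanMass", "CyclomaticNumber"
  )
  ac <- c(
    paste0("ATS", rep(AC_LAGS, times = length(AC_WEIGHTS)), rep(AC_WEIGHTS, each = length(AC_LAGS))),
    paste0("AATS", rep(AC_LAGS, times = length(AC_WEIGHTS)), rep(AC_WEIGHTS, each = length(AC_LAGS))),
    paste0("MATS", rep(AC_LAGS, times = length(AC_WEIGHTS)), rep(AC_WEIGHTS, each = length(AC_LAGS))),
    paste0("GATS", rep(AC_LAGS, times = length(AC_WEIGHTS)), rep(AC_WEIGHTS, each = length(AC_LAGS)))
  )
  types <- c(
    "nAromC", "nAromN", "nAromO", "nAromS", "nAliphN", "nAliphO",
    "nCarbonylC", "nCarboxyl", "nNitroN", "nHydroxyl", "nEtherO",
    "nPrimaryAmine", "nAmide", "nNitrile", "nSulfonyl", "nThioether",
    "nQuatC", "nCH3", "nCH2", "nCH1", "nAromCH", "nHalogenOnArom",
    "nOnAromSub", "nRingAtoms", "nTerminalAtoms"
  )
  phys <- c("logP", "TPSA", "MR", "HBA1", "HBA2", "HBD_jl")
  c(consts, topo, ac, types, phys)
}

# topological distance matrix via boolean reachability expansion
topo_dist <- function(n, bonds) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(bonds) == 0L) return(D)
  A <- matrix(FALSE, n, n)
  A[cbind(bonds$a1, bonds$a2)] <- TRUE
  A[cbind(bonds$a2, bonds$a1)] <- TRUE
  D[A] <- 1
  reach <- A
  k <- 1L
  while (any(is.infinite(D)) && k < n) {
    k <- k + 1L
    reach <- (reach %*% A) > 0
    new <- reach & is.infinite(D)
    diag(new) <- FALSE
    if (!any(new)) break
    D[new] <- k
  }
  D
}

autocorrelation_block <- function(D, w) {
  finite <- is.finite(D)
  n <- length(w)
  wc <- w - mean(w)
  denom_moran <- sum(wc^2) / n
  denom_geary <- sum(wc^2) / (n - 1)
  out <- numeric(length(AC_LAGS) * 4)
  for (li in seq_along(AC_LAGS)) {
    lag <- AC_LAGS[li]
    idx <- which(D == lag & upper.tri(D), arr.ind = TRUE)
    m <- nrow(idx)
    ats <- if (m) sum(w[idx[, 1]] * w[idx[, 2]]) else 0
    aats <- if (m) ats / m else NA_real_
    mats <- if (m && denom_moran > 0) {
      (sum(wc[idx[, 1]] * wc[idx[, 2]]) / m) / denom_moran
    } else NA_real_
    gats <- if (m && denom_geary > 0) {
      (sum((w[idx[, 1]] - w[idx[, 2]])^2) / (2 * m)) / denom_geary
    } else NA_real_
    out[li] <- ats
    out[length(AC_LAGS) + li] <- aats
    out[2 * length(AC_LAGS) + li] <- mats
    out[3 * length(AC_LAGS) + li] <- gats
  }
  out
}

descriptors_one <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  n <- nrow(at)
  m <- nrow(bd)
  deg <- at$degree
  D <- topo_dist(n, bd)
  dfin <- D[upper.tri(D)]
  dfin <- dfin[is.finite(dfin)]
  n_comp <- graph_components(n, bd)
  n_rings <- m - n + n_comp

  mass <- ATOMIC_MASS[at$symbol]
  en <- ELECTRONEGATIVITY[at$symbol]
  ion <- IONIZATION_EV[at$symbol]

  ring_atom <- rep(FALSE, n)
  if (m) {
    on_ring <- in_same_ring(bd, n)
    ring_atom[unique(c(bd$a1[on_ring], bd$a2[on_ring]))] <- TRUE
  }
  rot <- if (m) {
    bd$order == 1 & !in_same_ring(bd, n) & deg[bd$a1] > 1 & deg[bd$a2] > 1
  } else logical(0)

  neigh_sym <- function(i) {
    js <- c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])
    at$symbol[js]
  }
  has_double_O <- vapply(seq_len(n), function(i) {
    js <- c(bd$a2[bd$a1 == i & bd$order == 2], bd$a1[bd$a2 == i & bd$order == 2])
    any(at$symbol[js] == "O")
  }, logical(1))

  carbonyl <- at$symbol == "C" & has_double_O
  carboxyl <- vapply(seq_len(n), function(i) {
    if (at$symbol[i] != "C" || !has_double_O[i]) return(FALSE)
    js <- c(bd$a2[bd$a1 == i & bd$order == 1], bd$a1[bd$a2 == i & bd$order == 1])
    any(at$symbol[js] == "O" & at$n_hydrogens[js] > 0)
  }, logical(1))
  nitro <- at$symbol == "N" & at$charge == 1 & has_double_O
  hydroxyl <- at$symbol == "O" & at$n_hydrogens > 0 & !at$aromatic
  ether <- at$symbol == "O" & at$n_hydrogens == 0 & deg == 2 & !at$aromatic
  prim_amine <- at$symbol == "N" & at$n_hydrogens == 2 & !at$aromatic
  amide <- vapply(seq_len(n), function(i) {
    at$symbol[i] == "N" && any(carbonyl[c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])])
  }, logical(1))
  nitrile <- at$symbol == "N" & vapply(seq_len(n), function(i) {
    any(bd$order[bd$a1 == i | bd$a2 == i] == 3)
  }, logical(1))
  sulfonyl <- at$symbol == "S" & vapply(seq_len(n), function(i) {
    js2 <- c(bd$a2[bd$a1 == i & bd$order == 2], bd$a1[bd$a2 == i & bd$order == 2])
    sum(at$symbol[js2] == "O") >= 2
  }, logical(1))
  thioether <- at$symbol == "S" & deg == 2 & at$n_hydrogens == 0 & !at$aromatic & !sulfonyl
  halogen <- at$symbol %in% c("F", "Cl", "Br", "I")
  hal_on_arom <- halogen & vapply(seq_len(n), function(i) {
    any(at$aromatic[c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])])
  }, logical(1))
  o_on_arom <- at$symbol == "O" & !at$aromatic & vapply(seq_len(n), function(i) {
    any(at$aromatic[c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])])
  }, logical(1))

  consts <- c(
    nAtoms = n, nBonds = m, nH = sum(at$n_hydrogens),
    MW = sum(mass + at$n_hydrogens * ATOMIC_MASS[["H"]]),
    nRings = n_rings, nAromAtoms = sum(at$aromatic),
    fAromAtoms = sum(at$aromatic) / n, nAromBonds = sum(bd$aromatic),
    nC = sum(at$symbol == "C"), nN = sum(at$symbol == "N"),
    nO = sum(at$symbol == "O"), nS = sum(at$symbol == "S"),
    nP = sum(at$symbol == "P"), nF = sum(at$symbol == "F"),
    nCl = sum(at$symbol == "Cl"), nBr = sum(at$symbol == "Br"),
    nI = sum(at$symbol == "I"), nB = sum(at$symbol == "B"),
    nSi = sum(at$symbol == "Si"),
    nHet = sum(at$symbol != "C"), fHet = sum(at$symbol != "C") / n,
    nHalogen = sum(halogen),
    nPosCharge = sum(at$charge > 0), nNegCharge = sum(at$charge < 0),
    nSp = sum(at$hybridization == 1), nSp2 = sum(at$hybridization == 2),
    nSp3 = sum(at$hybridization == 3), nRotBonds = sum(rot),
    nHBDon = sum(at$symbol %in% c("N", "O") & at$n_hydrogens > 0),
    nHBAcc = sum(at$symbol %in% c("N", "O")),
    nSingleBonds = sum(bd$order == 1), nDoubleBonds = sum(bd$order == 2),
    nTripleBonds = sum(bd$order == 3), nConjBonds = sum(bd$conjugated)
  )

  # topological indices on the heavy-atom graph
  wiener <- if (length(dfin)) sum(dfin) else NA_real_
  p2 <- sum(D == 2 & upper.tri(D), na.rm = TRUE)
  p3 <- sum(D == 3 & upper.tri(D), na.rm = TRUE)
  ecc <- apply(D, 1, function(r) max(r[is.finite(r)]))
  zag2 <- if (m) sum(deg[bd$a1] * deg[bd$a2]) else NA_real_
  randic <- if (m) sum(1 / sqrt(deg[bd$a1] * deg[bd$a2])) else NA_real_
  balaban <- if (m && n_comp == 1L && n > 2) {
    s <- rowSums(ifelse(is.finite(D), D, 0))
    mu <- m - n + 1
    (m / (mu + 1)) * sum(1 / sqrt(s[bd$a1] * s[bd$a2]))
  } else NA_real_
  kappa1 <- if (m) (n * (n - 1)^2) / m^2 else NA_real_
  kappa2 <- if (p2 > 0) ((n - 1) * (n - 2)^2) / p2^2 else NA_real_
  topo <- c(
    Wiener = wiener,
    MeanDist = if (length(dfin)) mean(dfin) else NA_real_,
    Diameter = max(ecc), Radius = min(ecc),
    Harary = if (length(dfin)) sum(1 / dfin) else NA_real_,
    Zagreb1 = sum(deg^2), Zagreb2 = zag2, Randic = randic,
    BalabanJ = balaban,
    Platt = if (m) sum(deg[bd$a1] + deg[bd$a2] - 2) else NA_real_,
    P2 = p2, P3 = p3, Kappa1 = kappa1, Kappa2 = kappa2,
    GraphDensity = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
    MeanDeg = mean(deg), MaxDeg = max(deg),
    TotalEN = sum(en), MeanMass = mean(mass),
    CyclomaticNumber = n_rings
  )

  ac <- c(
    autocorrelation_block(D, unname(mass)),
    autocorrelation_block(D, unname(en)),
    autocorrelation_block(D, unname(ion)),
    autocorrelation_block(D, as.numeric(deg))
  )
  # interleave handled by name order: compute per weight then reorder to the
  # family-major layout of descriptor_names()
  nl <- length(AC_LAGS)
  per_w <- matrix(ac, nrow = 4 * nl)   # col = weight
  fam <- function(f) as.vector(per_w[((f - 1) * nl + 1):(f * nl), ])
  ac_ordered <- c(fam(1), fam(2), fam(3), fam(4))
  names(ac_ordered) <- grep("^(ATS|AATS|MATS|GATS)", descriptor_names(),
                            value = TRUE)

  types <- c(
    nAromC = sum(at$aromatic & at$symbol == "C"),
    nAromN = sum(at$aromatic & at$symbol == "N"),
    nAromO = sum(at$aromatic & at$symbol == "O"),
    nAromS = sum(at$aromatic & at$symbol == "S"),
    nAliphN = sum(!at$aromatic & at$symbol == "N"),
    nAliphO = sum(!at$aromatic & at$symbol == "O"),
    nCarbonylC = sum(carbonyl), nCarboxyl = sum(carboxyl),
    nNitroN = sum(nitro), nHydroxyl = sum(hydroxyl), nEtherO = sum(ether),
    nPrimaryAmine = sum(prim_amine), nAmide = sum(amide),
    nNitrile = sum(nitrile), nSulfonyl = sum(sulfonyl),
    nThioether = sum(thioether),
    nQuatC = sum(at$symbol == "C" & deg == 4),
    nCH3 = sum(at$symbol == "C" & at$n_hydrogens == 3),
    nCH2 = sum(at$symbol == "C" & at$n_hydrogens == 2 & !at$aromatic),
    nCH1 = sum(at$symbol == "C" & at$n_hydrogens == 1 & !at$aromatic),
    nAromCH = sum(at$aromatic & at$symbol == "C" & at$n_hydrogens == 1),
    nHalogenOnArom = sum(hal_on_arom),
    nOnAromSub = sum(o_on_arom),
    nRingAtoms = sum(ring_atom),
    nTerminalAtoms = sum(deg <= 1)
  )

  c(consts, topo, ac_ordered, types)
}

graph_components <- function(n, bonds) {
  comp <- seq_len(n)
  if (nrow(bonds)) {
    repeat {
      changed <- FALSE
      for (j in seq_len(nrow(bonds))) {
        a <- comp[bonds$a1[j]]; b <- comp[bonds$a2[j]]
        if (a != b) {
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  length(unique(comp))
}

# OpenBabel physchem properties, batched (one CLI call for the whole set)
ob_physchem <- function(smiles) {
  n <- length(smiles)
  res <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("logP", "TPSA", "MR", "HBA1", "HBA2", "HBD_jl")))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles[ok], paste0("m", which(ok))), infile)
  out <- suppressWarnings(system2(
    OB_BIN, c(infile, "-osmi", "-e", "--append", shQuote("logP TPSA MR HBA1 HBA2 HBD")),
    stdout = TRUE, stderr = FALSE
  ))
  parts <- stringr::str_match(
    out, "\\sm(\\d+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*$")
  hit <- !is.na(parts[, 1])
  idx <- as.integer(parts[hit, 2])
  vals <- apply(parts[hit, 3:8, drop = FALSE], 2, as.numeric)
  res[idx, ] <- vals
  res
}
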