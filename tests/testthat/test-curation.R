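test_that("canonicalization is idempotent and collapses equivalent renderings", {
  can <- canonicalize_smiles(c("OCC", "C(C)O", "CCO"))
  expect_length(unique(can), 1)
  expect_equal(canonicalize_smiles(can), can)
  # aromatic perception: the Kekule form maps to the aromatic rendering
  benz <- canonicalize_smiles("C1=CC=CC=C1")
  expect_equal(benz, canonicalize_smiles("c1ccccc1"))
  expect_true(grepl("c", benz))
})

test_that("canonical partition agrees with an independent toolkit", {
  # RDKit (Python) as the independent oracle: two SMILES are equivalent under
  # our canonicalization iff they are equivalent under RDKit's
  pairs <- list(c("OCC", "CCO"), c("C1=CC=CC=C1", "c1ccccc1"),
                c("N(C)C", "CNC"), c("CCO", "CCN"), c("c1ccncc1", "c1ccccc1"))
  ours <- vapply(pairs, function(p) {
    cc <- canonicalize_smiles(p); cc[1] == cc[2]
  }, logical(1))
  script <- paste0(
    "from rdkit import Chem\n",
    "import sys\n",
    "pairs=", "[", paste(vapply(pairs, function(p) {
      sprintf("('%s','%s')", p[1], p[2])
    }, character(1)), collapse = ","), "]\n",
    "for a,b in pairs:\n",
    "    print(int(Chem.CanonSmiles(a)==Chem.CanonSmiles(b)))\n")
  f <- tempfile(fileext = ".py"); writeLines(script, f)
  theirs <- as.logical(as.integer(system2("python", f, stdout = TRUE)))
  expect_equal(ours, theirs)
})

test_that("unparsable SMILES fail loudly or map to NA", {
  expect_true(is.na(canonicalize_smiles("not_a_smiles")))
  expect_error(canonicalize_smiles(""), "empty")
})

test_that("strip_to_parent keeps the largest fragment and removes stereo", {
  p <- strip_to_parent(canonicalize_smiles("[Na+].CC(=O)[O-]"))
  expect_false(grepl("Na", p))
  expect_true(grepl("O-", p, fixed = TRUE))     # acetate anion kept as ion
  # stereo removal: collapses to the achiral canonical form
  ala <- strip_to_parent(canonicalize_smiles("C[C@H](N)C(=O)O"))
  expect_equal(ala, canonicalize_smiles("CC(N)C(=O)O"))
  expect_false(grepl("@", ala, fixed = TRUE))
  # single achiral fragment unchanged
  expect_equal(strip_to_parent("CCO"), "CCO")
})

test_that("curate_compounds merges duplicates and logs failures", {
  recs <- data.frame(
    id = c("id1", "id2", "id3", "id4", "id5"),
    smiles = c("OCC", "CCO", "not_a_smiles", "[Na+].CC(=O)[O-]", "CC(=O)O")
  )
  cur <- curate_compounds(recs)
  expect_equal(nrow(cur), 3)  # ethanol (merged), acetate anion, acetic acid
  eth <- cur[cur$canonical_smiles == "CCO", ]
  expect_setequal(eth$source_ids[[1]], c("id1", "id2"))
  expect_true("merged_duplicate" %in% eth$flags[[1]])
  rej <- curation_rejections(cur)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$reason, "parse_failure")
  # acetate anion and acetic acid stay distinct structures
  expect_equal(sum(grepl("O-", cur$canonical_smiles, fixed = TRUE)), 1)
})

test_that("curation is idempotent and order-invariant", {
  b <- small_benchmark()
  smi <- b$lib$canonical_smiles[1:40]
  recs <- data.frame(id = paste0("c", 1:40), smiles = smi)
  cur1 <- curate_compounds(recs)
  # idempotence on the compound set
  cur2 <- curate_compounds(data.frame(id = cur1$canonical_smiles,
                                      smiles = cur1$canonical_smiles))
  expect_equal(cur2$canonical_smiles, cur1$canonical_smiles)
  # permutation invariance
  perm <- sample(nrow(recs))
  cur3 <- curate_compounds(recs[perm, ])
  expect_equal(cur3$canonical_smiles, cur1$canonical_smiles)
  # round trip: parse -> write -> parse is stable
  expect_equal(canonicalize_smiles(cur1$canonical_smiles), cur1$canonical_smiles)
})

test_that("element whitelist screens exotic structures", {
  recs <- data.frame(id = c("a", "b"), smiles = c("CC[Se]CC", "CCO"))
  cur <- curate_compounds(recs)
  expect_equal(nrow(cur), 1)
  expect_equal(curation_rejections(cur)$reason, "element_outside_whitelist")
})
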