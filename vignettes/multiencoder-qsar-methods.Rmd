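---
title: "Multi-encoder QSAR for cardiotoxicity AOP endpoints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-encoder QSAR for cardiotoxicity AOP endpoints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Cardiotoxic hazard can be organised along an adverse outcome pathway (AOP):
a molecular initiating event — here the inhibition of mitochondrial
complexes (MIE1) — triggers key events such as increased oxidative stress
(KE1) and mitochondrial dysfunction (KE2), which propagate to organ-level
harm. Each event is measurable by a panel of in vitro assays, and each assay
reports a binary *hit call* per chemical. `aopqsar` builds binary
structure–activity (QSAR) classifiers for such endpoints: given a chemical's
structure (as SMILES) it predicts the probability that the chemical is
active for the endpoint.

The pipeline is: curate structures → aggregate hit calls into endpoint
labels → encode chemistry (five representations) → split with class
stratification → handle imbalance (oversampling or output-bias
initialisation) and optionally augment → train a model battery →
applicability-domain screening → six-metric evaluation → explainability.

## Data model and curation

Raw inputs are a compound table (identifier + SMILES) and a wide hit-call
matrix (one row per compound, one column per assay, values
active/inactive/missing). Curation (`curate_compounds()`):

* canonicalization (OpenBabel canonical SMILES);
* salt stripping: keep the largest disconnected fragment. Ties on
  heavy-atom count break by molecular weight, then lexicographic canonical
  SMILES, so results are order-independent;
* stereochemistry removal (tetrahedral and double-bond markers; isotopes
  are kept);
* an *inconsistency* screen, operationalised as: parse/sanitisation
  failure, empty structure after stripping, or elements outside a
  configurable organic whitelist (C, N, O, S, P, halogens, B, Si, H).
  Counter-ion-only records survive as the ion itself when the ion parses —
  whether such records should be dropped instead is a judgement call; the
  whitelist keeps the rule transparent and configurable;
* duplicate structures merge into one compound carrying all source
  identifiers; rejected records go to a rejection log, never silently away.

Endpoint labels follow the any-hit rule (`aggregate_hitcalls()`): a
compound is active for an endpoint if at least one of the endpoint's assays
reports an active call. "Inactive" requires every *observed* call to be
inactive; compounds with no observed call among the endpoint's assays are
excluded and logged. The rule is monotone — adding assays can only turn
inactives active — which the tests assert as a property. Summary
percentages round half away from zero to integers, matching how such
tables are conventionally printed.

## The five chemical representations

1. **Molecular descriptors** (`compute_descriptors()`): a fixed-width 1-2D
   set computed in the package — constitutional counts, topological indices
   (Wiener, Zagreb, Randić, Balaban J, Kier shape), Moreau–Broto / Moran /
   Geary autocorrelations over atomic mass, electronegativity, first
   ionisation energy and degree (lags 1–6), atom-type counts, and OpenBabel
   physico-chemical properties (logP, TPSA, molar refractivity, H-bond
   counts). Cells that cannot be computed (degenerate graphs, missing lags
   on small molecules) are `NA` and left to preprocessing. The width is
   fixed for every molecule.
2. **Circular fingerprints** (`compute_circular_fp()`): hashed
   extended-connectivity environments up to radius 2, folded to 2048 bits
   (both configurable). Radius 2 / 2048 bits is the de-facto standard
   ECFP4 setting.
3. **MACCS keys** (`compute_maccs_fp()`): the 166 public structural keys.
4. **Molecular graphs** (`featurize_graph()`): heavy atoms as nodes with
   atomic number, valence, bonded hydrogen count and a hybridisation code;
   bonds as undirected edges (stored once; message passing expands them to
   both directions) with bond order and a conjugation flag. Conjugation is
   granted when both end atoms carry a π system (sp²/sp or aromatic).
5. **Tokenized SMILES + latent codes**: character-level tokenization
   against a corpus vocabulary (`build_vocabulary()`), padded/truncated to
   the nearest-rank 95th percentile of corpus string lengths. Single
   characters are the tokens, so two-letter elements split — consistent
   with character-level vectorization. The vocabulary reserves padding,
   unknown and sequence-delimiter specials; sequences themselves are raw
   characters padded on the right. Latent codes come through a pluggable
   encoder interface (`latent_encode()`): a deterministic hashed
   character-n-gram projection (no training), a small dense autoencoder
   trainable on any SMILES corpus, or any user object with a `predict`
   method of fixed output width (e.g. a pretrained sequence autoencoder).

**Feature preprocessing** (`preprocess_features()`) applies to descriptors
and latent codes only: drop features with training variance below 0.1, then
greedily drop one of each pair with |Pearson r| > 0.9 (features visited by
descending variance, the later one dropped — the thresholds are the method's
convention, the visiting order is ours and configurable), impute remaining
missing cells by the training median, and standardise to zero mean / unit
variance. The fitted state transforms held-out data unchanged; no held-out
statistic can leak in. Fingerprints, graphs and token sequences are used
raw.

## Class imbalance

Endpoint datasets are imbalanced (the KE2-sized benchmark is 23% active).
Two strategies, mirroring common practice:

* **Baseline ML models**: minority oversampling on training data only.
  `oversample()` implements SMOTE and its Borderline-1/2, SVM and k-means
  variants; every synthetic point is a convex combination
  `x_i + u (x_nn − x_i)` of two minority neighbours (`u ~ U(0,1)`;
  Borderline-2 halves `u` to stay near the seed). Defaults: `k_neighbors =
  5`, resampling to a 1:1 ratio. `distribution_shift_report()` compares
  original and resampled feature distributions (two-sample KS statistic,
  flag above 0.2 by default — reported, never blocking).
* **Networks**: the output layer's bias starts at `log(p/(1−p))` of the
  training class ratio, and the output weights start at zero so the initial
  prediction is exactly the base rate; this removes the early-training
  advantage of the majority class without altering the data.

## SMILES-enumeration augmentation

`enumerate_smiles()` renders the same molecule as different strings by
random atom-rank permutation of the connection table before writing a
non-canonical SMILES. `augment_training_set()` gives each training compound
its canonical form plus up to `factor − 1` distinct variants (default
factor 10); variants inherit the parent label, and the function refuses to
run on anything not marked as a training partition. Enumeration feeds the
sequence models only — tabular encoders are invariant to it by
construction, and the tests assert that curating an augmented set collapses
exactly back to the parents.

## Applicability domain

Five methods fit on training features (tabular encoders only): bounding
box, bounding box on principal components (components covering 95%
variance), leverage (`h = x'(X'X)⁻¹x`, threshold `3p/n`, ridge fallback on a
singular cross-product), distance from centroid (threshold = maximum
training distance), and a variable-k nearest-neighbour method (per-point
mean distance to `k ≈ n^{1/3}` neighbours, calibrated at the 95th
percentile of the training distribution of those distances; `k` and the
quantile are exposed). The consensus rule is deliberately permissive: a
test compound is discarded only when *every* method of *every* encoder
places it outside. On queries drawn from the training distribution the
discard rate is ~0; on deliberately shifted queries it approaches 1 —
both are asserted in the tests.

## The model battery

Eight baseline families behind one `build_model()` / `train_model()` /
`predict()` surface: regularised logistic regression (ridge, small
penalty), decision tree, random forest, balanced random forest (per-class
balanced bootstraps), extreme gradient boosting, SVM (RBF, probability
outputs), k-nearest neighbours, and Gaussian naive Bayes. Backing learners
come from the standard R stack (glmnet, rpart, ranger, xgboost, e1071,
class); hyperparameters are config-exposed with conventional defaults.

Four network families share a training protocol — mini-batches of 32, 10%
stratified validation split, Adam at 1e-3, learning rate divided by 10 when
the validation loss plateaus for 10 epochs, stop at the second plateau:

* **dnn**: dense stacks with ReLU and dropout 0.2; hidden widths must be
  powers of two (defaults 512-256-128);
* **nlp_seq**: token embedding (64) → LSTM(128, sequences) → GRU(64) →
  dense head;
* **mpnn**: 3 message-passing rounds in which each atom aggregates
  ReLU-transformed messages from its neighbours (bond features
  concatenated), a GRU-cell state update with weights shared across
  rounds, mean readout over atoms, dense head; `rounds = 0` is a legal
  degenerate baseline that reads out raw node embeddings;
* **multimodal**: five branches — MACCS, circular fingerprints,
  descriptors, tokenized SMILES, latent codes — each a dense stack (the
  token branch embeds and mean-pools before its dense stack), merged by
  concatenation into a dense head and trained jointly.

The engine behind these is a compact manually-differentiated network
library inside the package (dense, dropout, embedding, LSTM, GRU,
mean-pooling and message-passing layers with Adam). Every layer's
gradients are validated against central finite differences in the test
suite (tolerance 1e-6 absolute on small problems). The token branch of the
multimodal network mean-pools embeddings rather than running a recurrent
stack; this keeps joint training of five branches affordable while the
standalone sequence model retains the full recurrent architecture.

## Validation protocol

* `stratified_split()`: the test size is `round(N · fraction)` (round half
  away from zero — this reproduces published train/test tables exactly for
  the three endpoint sizes); per-class test counts are the
  largest-remainder apportionment of proportional shares; a class that
  would get zero test compounds is forced to one with a warning.
* `repeated_kfold_cv()`: stratified k-fold (default 10×10); feature
  preprocessing and oversampling are fitted inside each training fold only;
  single-class folds trigger a logged redraw. The summary aggregates all
  k × iterations fold scores.
* `grid_search()`: exhaustive, 5-fold by default, winner by mean F1 with
  ties broken by mean balanced accuracy then grid order. F1 is the tuning
  metric because it remains informative under imbalance.
* `compute_metrics()`: balanced accuracy, precision, sensitivity,
  specificity, MCC and F1 from the confusion counts; all zero-denominator
  cases return 0 (including MCC). The formulas are checked against a
  brute-force element-by-element confusion enumeration on 1000 random
  vectors.
* Explainability: `permutation_importance()` (metric drop after shuffling
  one column, mean ± sd over repeats; a constant column scores exactly
  zero) and `shap_summary()` — interventional Shapley values of the
  predicted probability, computed exactly by subset enumeration up to 12
  features and by Monte-Carlo permutation sampling beyond, with the
  additivity identity (base value + attributions = prediction) asserted.
  Shapley values are exact for linear models, which the tests exploit.

## The synthetic benchmark generator

Real endpoint datasets are assembled from public assay databases and cannot
ship with the package, so `generate_benchmark()` produces libraries with a
*planted, fully known* ground truth: molecules are assembled from a
fragment grammar (roughly 34 aromatic and 12 aliphatic scaffold templates ×
25 substituents over up to three attachment slots), and activity is defined
by a toxicophore — by default a nitroaromatic group, an arbitrary but
classical structural-alert choice. Actives carry it, inactives never do,
so substructure search reproduces the truth exactly at zero label noise.

Presets mirror the three endpoint datasets' sizes and imbalances — 232
compounds at 79% active (MIE1-like), 636 at 30% (KE1-like), 5004 at 23%
(KE2-like) — with class counts exact by construction. Assay matrices draw
each hit call independently with class-conditional probabilities (defaults:
hit probability 0.4 given active, 0.02 given inactive, 10% missing —
chosen so that a realistic any-hit aggregation is noisy per assay yet
nearly clean after aggregation over an endpoint's panel). The endpoint
dataset of a preset is built from the structural truth so the printed
sizes are exact; the noisy assay matrix exercises the labelling stage, and
`label_noise` flips a chosen fraction of labels for robustness
experiments.

What passing on this generator does and does not show: the planted signal
is a single local substructure, which fingerprint and sequence models
detect almost perfectly — hence the near-ceiling accuracies in the checks.
Real assay endpoints mix many weak mechanisms, carry label errors from
curve fitting, and span a far larger chemical space; absolute accuracies
here say nothing about performance on real data. What the benchmarks *do*
validate is the machinery: leakage-free splits and folds, label
aggregation, imbalance handling, that every encoder carries enough signal
to learn from, and that the fusion and augmentation paths do not lose
information available to their single-encoder counterparts.

## Problem sizes used in the checks

The acceptance checks run the full KE2-sized benchmark (5004 compounds)
for split arithmetic, summaries, the fingerprint baseline and the
applicability-domain consensus. The network comparisons run on reduced
draws with the same 23% imbalance — 900 compounds for the multimodal
versus single-branch comparison and 400 parents (≈3500 sequences after
factor-10 enumeration) for the augmentation comparison, with branch widths
128/64 and 25–30 epoch caps — sizes at which the pure-R training loops
converge in minutes while the compared quantities are stable.

## Numerical and design notes

* Canonicalization, fingerprints and SMARTS matching run through OpenBabel
  in one batched process call per operation; parsed hex fingerprints were
  verified bit-for-bit against the per-molecule API.
* The V2000 connection table is parsed directly (including `M  CHG` formal
  charges, which supersede legacy atom-line codes); implicit hydrogens
  derive from charge-adjusted standard valences with hypervalent S/P
  handled; aromaticity comes from the SMILES rendering itself (atom order
  is preserved through the conversion).
* The descriptor calculator defines its own fixed set; it is *not* the
  1613-descriptor reference calculator used in large published QSAR
  studies, and analyses that compare descriptor counts should treat the
  two as different instruments.
* Enumeration retries random permutations up to 10× the requested count
  and returns fewer variants when a molecule admits fewer distinct
  renderings (single atoms return only themselves).
* Seeds: every stochastic step takes an explicit seed; the pipeline
  expands one global seed into per-stage seeds by a fixed counter scheme
  (`stage offset × 100`), so any stage can be reproduced in isolation.
* Probability 0.5 is the label threshold, with `≥` breaking the boundary
  towards active.

## Known limitations

* OpenBabel's canonical SMILES, MACCS implementation and ECFP hashing
  differ from other toolkits'; models and fingerprints are internally
  consistent but not bit-compatible with RDKit-derived ones.
* The descriptor set is a few hundred wide, adequate for the bundled
  benchmarks but narrower than dedicated descriptor engines.
* The network engine is plain R: fine at the benchmark sizes above,
  not intended for datasets orders of magnitude larger.
* Tautomer standardisation and charge neutralisation are out of scope of
  curation; stereochemistry is deliberately discarded, so enantiomer pairs
  collapse to one record.
* kNN-based AD and SMOTE use dense distance matrices — appropriate for
  thousands, not millions, of compounds.
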