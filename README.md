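# aopqsar

Multi-encoder QSAR modelling of adverse-outcome-pathway (AOP)
cardiotoxicity endpoints in R.

Chemicals can injure the heart through a cascade the AOP framework makes
explicit: a molecular initiating event — inhibition of mitochondrial
complexes (MIE1) — drives key events such as increased oxidative stress
(KE1) and mitochondrial dysfunction (KE2). Each event is observable through
a panel of in vitro assays that report a binary *hit call* per chemical.
`aopqsar` is for computational toxicologists who want to turn such assay
panels into structure-based classifiers: it takes raw SMILES and a hit-call
matrix and produces, per endpoint, trained models that predict the
probability a new structure is active.

The package implements the full workflow:

* **Curation** — SMILES canonicalization, salt stripping to the largest
  fragment, stereochemistry removal, an element-whitelist error screen,
  duplicate merging with a rejection log (`curate_compounds()`).
* **Labelling** — the any-hit rule: a compound is active for an endpoint
  when at least one of the endpoint's assays calls it active; all-missing
  compounds are excluded and logged (`aggregate_hitcalls()`).
* **Five chemical representations** — 1-2D molecular descriptors, circular
  (ECFP-style) fingerprints, MACCS keys, molecular graphs, tokenized
  SMILES, and pluggable latent codes (`compute_descriptors()`,
  `compute_circular_fp()`, `compute_maccs_fp()`, `featurize_graph()`,
  `build_vocabulary()` / `vectorize_smiles()`, `latent_encode()`), with
  variance / correlation / standardisation preprocessing fitted on training
  data only (`preprocess_features()`).
* **Imbalance handling** — SMOTE and its Borderline-1/2, SVM and k-means
  variants for the baseline models (`oversample()`), output-bias
  initialisation for the networks, and a distribution-shift report.
* **SMILES-enumeration augmentation** — alternative renderings of the same
  molecule, training-partition only (`enumerate_smiles()`,
  `augment_training_set()`).
* **A model battery** — logistic regression, decision tree, random forest,
  balanced random forest, gradient boosting, SVM, kNN, Gaussian naive
  Bayes, a dense network, a character-level LSTM/GRU sequence model, a
  message-passing graph network, and a five-branch multimodal fusion
  network, all behind one `build_model()` / `train_model()` / `predict()`
  surface.
* **Applicability domain** — bounding box, PCA bounding box, leverage,
  centroid distance and variable-k kNN, with the permissive consensus that
  discards a test compound only when every method of every encoder places
  it outside (`fit_ad()`, `assess()`, `ad_consensus()`).
* **Evaluation & explainability** — stratified splits that reproduce
  published train/test tables exactly, repeated stratified k-fold CV with
  in-fold preprocessing/oversampling, grid search on F1, the six-metric
  confusion report (balanced accuracy, precision, sensitivity,
  specificity, MCC, F1), permutation importance, and Shapley attributions
  (`stratified_split()`, `repeated_kfold_cv()`, `grid_search()`,
  `compute_metrics()`, `permutation_importance()`, `shap_summary()`).
* **A synthetic benchmark generator** — compound libraries with a planted
  nitroaromatic toxicophore and assay matrices with class-conditional hit
  probabilities, in presets matching the three endpoint datasets' sizes
  and imbalances (232 @ 79% active, 636 @ 30%, 5004 @ 23%)
  (`generate_benchmark()`).

The classifier core, for a compound *x* with binary activity *y*: each
encoder *E* maps *x* to features *E(x)*; a model *f* estimates
*p(y = 1 | E(x))*; labels use *p ≥ 0.5*. The multimodal network learns
five branch embeddings *h₁…h₅* (MACCS, circular FP, descriptors, token
sequence, latent code) and fuses them by concatenation,
*p = σ(g([h₁; …; h₅]))*, trained jointly. Performance is reported as the
six confusion-matrix metrics; balanced accuracy (the mean of sensitivity
and specificity) is the headline number under class imbalance.

## Worked example

Generate a KE1-sized benchmark (636 compounds, 30% active), split 90–10,
train a random forest on circular fingerprints, evaluate:

```r
library(aopqsar)

bench <- generate_benchmark("ke1_like", seed = 7)
bench$summary
#> # A tibble: 1 × 6
#>   endpoint     n n_active n_inactive pct_active pct_inactive
#> 1 KE1        636      191        445         30           70

split <- stratified_split(bench$dataset, test_fraction = 0.1, seed = 1)
fp_train <- compute_circular_fp(split$train)
fp_test  <- compute_circular_fp(split$test)

model <- build_model(model_spec("rforest", "circular_fp", seed = 1))
model <- train_model(model, list(X = fp_train$matrix, y = split$train$active))
compute_metrics(split$test$active, predict(model, fp_test$matrix) >= 0.5)
#>   balanced_accuracy precision sensitivity specificity   mcc    f1
#> 1                 1         1           1           1     1     1

fit_fun <- function(X, y) {
  train_model(build_model(model_spec("rforest", "circular_fp", seed = 1)),
              list(X = X, y = y))
}
cv <- repeated_kfold_cv(fp_train$matrix, split$train$active, fit_fun,
                        k = 5, iterations = 2, seed = 3)
glance(cv)
#>   balanced_accuracy    f1   mcc precision sensitivity specificity n_folds
#> 1                 1     1     1         1           1           1      10
```

The perfect scores are a property of the benchmark, not of the model: the
generator plants a single nitroaromatic toxicophore that defines activity,
and circular fingerprints encode exactly such local substructures. The 636
compounds split into 572 train / 64 test, with the 30/70 class balance
preserved in both partitions; the CV table aggregates all 5 × 2 fold
scores. On real assay data, where activity mixes many weak mechanisms,
these numbers land far below 1 — the methods vignette
(`vignettes/multiencoder-qsar-methods.Rmd`) discusses what the synthetic
benchmarks do and do not demonstrate.

`autoplot()` methods cover CV results, training histories, permutation
importances, Shapley summaries and split-series pipeline results;
`tidy()`/`glance()` give broom-style tables. `run_pipeline()` drives the
whole workflow from a YAML/list configuration, and
`inst/scripts/aopqsar-cli.R` wraps curation, augmentation and pipeline runs
for the shell.

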