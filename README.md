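# noderad

Interpretable radiomics for lymph-node status prediction on
contrast-enhanced CT.

## What this is for

Whether a metastatic neck lymph node shows **extranodal extension**
(ENE — tumor breaching the nodal capsule) changes treatment decisions
in head-and-neck squamous cell carcinoma, but CT reads of ENE are
unreliable. `noderad` implements a transparent alternative to black-box
image models, aimed at researchers who need predictions they can trace
back to named quantities:

1. **Feature extraction.** Each contoured node yields a fixed catalog
   of **460 features in 26 subsets**: 18 gray-level co-occurrence
   statistic types × 20 (distance 1–5 px × angle 0°/45°/90°/135°)
   configurations on the 16-level quantized largest inscribed square,
   11 size-zone features, 11 first-order gray statistics, 24 2D and 29
   3D shape features from an isotropic surface model, 6 boundary
   contrast features at each band radius (3/5/10 px), and 7 Hu
   invariant moments.
2. **Coarse-to-fine feature selection.** Subsets are first ranked by
   stratified 10-fold cross-validated SVM accuracy on three tasks
   (metastatic vs normal, ENE vs rest, three-class); the top-5 union
   forms the candidate pool. An **inheritable bi-objective
   combinatorial genetic algorithm (IBCGA)** then selects exactly *r*
   features while co-tuning the SVM cost *C* and RBF width *γ*,
   maximizing the 10-fold CV accuracy

   *fitness(X, C, γ) = acc₁₀CV(SVM(C, γ; features X))*,

   with *r* inherited downward from `r_start = 70` to `r_end = 5`
   (population 50, crossover 0.8 via orthogonal-array recombination,
   bit-swap mutation 0.05, 100 generations per phase). Selected
   features are ranked by **main-effect difference**
   MED(f) = fitness(X_m) − fitness(X_m \\ {f}).
3. **Ensemble.** 31 independently seeded IBCGA models vote; the
   plurality class wins, and the ENE / metastasis scores are the vote
   fractions.

A synthetic phantom generator reproduces the class-conditional trends
this classifier exploits (texture variance and small-area emphasis
largest in normal nodes, 3D solidity largest in ENE, boundary contrast
blurred by ENE), so the entire pipeline is testable without clinical
data.

## Worked example

A miniature version of the full pipeline (60 phantoms, reduced search
budget; a few minutes of CPU):

```r
library(noderad)

spec   <- phantom_spec(counts = c(normal = 20, metastatic = 20, ENE = 20), seed = 7)
cohort <- generate_cohort(spec)                 # 48 train / 12 test, stratified 8:2
tab    <- extract_table(cohort$nodes)           # 60 x 460 feature table
tab$split <- cohort$manifest$split
train <- subset(tab, split == "train"); test <- subset(tab, split == "test")

rank <- evaluate_subsets(train, folds = 5, seed = 7)
#> <subset_ranking>
#>   met-vs-normal: Contrast (1.000), Different Entropy (1.000), Different Variance (1.000), ...
#>   ene-vs-rest:   Contrast (1.000), Different Entropy (1.000), Different Variance (1.000), ...
#>   three-class:   Contrast (1.000), Different Entropy (1.000), Different Variance (1.000), ...
#>   pool: 5 subsets, 86 features

cfg <- ibcga_config(n_pop = 10, g_max = 3, r_start = 10, r_end = 4,
                    cv_folds = 5, seed = 7)     # reduced search budget
ens <- train_ensemble(train, pool = rank$pool_features, config = cfg, n_members = 7)
#> <noderad_ensemble> 7 members over a 86-feature pool

pred <- predict_ensemble(ens, test)
head(pred[, c("node_id", "normal", "metastatic", "ENE", "predicted", "ene_score")], 4)
#>         node_id normal metastatic ENE predicted ene_score
#> 1 normal_710017      7          0   0    normal         0
#> ...
mean(pred$predicted == test$label)
#> [1] 1                                          # 12/12 phantom test nodes

bv <- binary_views(pred, test$label)
confusion_metrics(bv$ene$pred, bv$ene$truth)
#> TP 4 FP 0 FN 0 TN 8 | acc 100.00% sens 100.00% spec 100.00% ppv 100.00% npv 100.00%
roc_auc(bv$ene$score, bv$ene$truth)$auc
#> [1] 100
```

On phantoms the classes are separable by construction, so perfect
scores are expected; the point of the example is the shape of the
workflow and of its outputs. Vote counts always sum to the member
count; `ene_score` is the ENE vote fraction, usable as an ROC score.
On clinical data, published accuracy for this model family is ~80% for
ENE detection on an independent test set — reproducing those numbers
requires the original private cohort and is out of scope here.

The same pipeline is scriptable from the shell (see
`inst/exec/noderad`): `simulate`, `extract`, `coarse-select`, `train`,
`predict`, `evaluate`, each writing a provenance JSON next to its
output.

## Package layout

- `R/preprocess.R`, `R/mesh.R` — windowing, rasterization, morphology,
  inscribed square, bands, isotropic 3D model + mesh utilities
- `R/catalog.R`, `R/texture.R`, `R/shape2d.R`, `R/shape3d.R` — the
  460-feature catalog and all extractors
- `R/svm.R`, `src/svm.cpp` — self-contained RBF C-SVC (SMO) and fused
  CV accuracy
- `R/coarse.R`, `R/ibcga.R`, `R/ensemble.R` — subset ranking, the
  IBCGA, the 31-model voting ensemble
- `R/synthetic.R` — phantom and planted-table generators
- `R/metrics.R`, `R/cli.R` — metrics and the command-line interface
- `vignettes/noderad-methods.Rmd` — the methods notes: every frozen
  convention, the generator's stated world, and known limitations
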