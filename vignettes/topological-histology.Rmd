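---
title: "Topological versus radiomic features for lung nodule histology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological versus radiomic features for lung nodule histology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topohist)
```

## The problem and the pipeline

Determining lung tumor histology (benign versus malignant, and between
malignant subtypes) from chest CT is usually approached with radiomic
features: quantitative descriptors of lesion intensity, shape and texture
computed from a segmented nodule. Persistent homology offers a complementary
description: it tracks *topological* events — connected components merging,
loops closing, voids filling in — as the image is thresholded at increasing
radiodensity, and summarizes them as persistence diagrams of (birth, death)
pairs. Cavitation, lobulation and spiculation, all of which radiologists
score visually, have natural topological signatures.

`topohist` implements the full benchmark pipeline:

1. **Synthetic cohorts** of CT-like nodules with planted class-conditional
   morphology, since real clinical cohorts cannot ship with a package.
2. **Five filtration objects** per scan: the lesion voxels (raw and
   negated), the lesion plus its surrounding boundary box (raw and negated),
   and a point cloud of the lesion surface.
3. **Persistence diagrams** in homology dimensions 0–2 for each object —
   5 × 3 = 15 diagrams per scan — via cubical sublevel filtrations for the
   grids and a Vietoris–Rips filtration for the cloud.
4. **Vectorization** into a fixed, named 290-entry feature vector.
5. **Evaluation**: mean-imputation, min–max scaling, 5-bin discretization,
   mRMR selection of 10 features, six model families, five feature/model
   combination strategies (`rad`, `top`, `concat`, `vote`, `stack`), and
   repeated cross-validation with stratified or patient-grouped folds.

## The synthetic generator

Each nodule is a solid ball of radius `base_radius_mm`, optionally unioned
with *lobulation* bumps (spheres of 0.45 r centered at 0.8 r in random
directions) and *spicules* (thin cylinders, radius ≈ 2 mm, reaching from
0.5 r to 1.6 r), minus *cavities*: spherical air-filled voids kept at least
3 mm of tissue away from the lesion boundary and from each other so the
planted dimension-2 topology survives digitization and resampling. Cavity
feasibility is enforced at draw time (a nodule carrying two cavities is at
least 7.5 mm in radius).

Intensities mimic Hounsfield units: lung-like background at −800 HU, lesion
tissue following a smooth radial profile (`intensity_mu` at the rim to
`intensity_mu + intensity_sigma` at the core, defaults placing lesions in
the +20…+60 HU range), both with additive Gaussian noise (sd 15 HU). The
default grid spacing is anisotropic, (0.7, 0.7, 2.5) mm, so the isotropic
resampling stage is exercised non-trivially.

Cohorts draw a patient-level class (A, benign-like; B, malignant-like),
give each patient a second nodule with probability `multi_nodule_rate`
(default 0.1), and draw per-nodule morphology from class-conditional
distributions: class B nodules are larger (8.5 ± 1.2 vs 7 ± 1.2 mm),
brighter (+45 vs +30 HU), more lobulated and spiculated, and always carry
1–2 internal cavities. The continuous malignancy score is a scaled logistic
function of the morphology plus Gaussian noise (sd 0.4 on the 1–5 scale,
leaving a recoverable but non-trivial r²), clipped to [1, 5].

Every generator is a pure function of its arguments and a seed. The planted
topology is auditable independently of the persistence machinery:
`betti_numbers()` labels foreground components and enclosed background
pockets by breadth-first search and derives the loop count from the Euler
characteristic of the voxel complex.

**What the generator does not emulate**: scanner reconstruction kernels and
texture, partial-volume effects, pleural attachment, vasculature, reader
segmentation variability, or anatomically realistic lung context. Passing
tests therefore demonstrate correctness of the machinery and recoverability
of planted morphological signal — not clinical performance on real CT.

## Filtration objects

All scans are first resampled to 1 × 1 × 1 mm (trilinear for intensities,
nearest-neighbor for masks — the standard radiomics convention). The lesion
grids set voxels outside the mask to +∞ ("never enters the filtration") and
are surrounded by a one-voxel +∞ border so boundary effects are uniform;
the boundary-box grids crop the full volume to the mask's bounding box
expanded by 2 voxels (the margin is configurable; nothing in the problem
fixes it). *Negation* is an arithmetic sign flip: the sublevel filtration of
−x is the superlevel filtration of x, making bright-core structure visible
to the same machinery. The surface cloud stacks, slice by axial slice, the
foreground voxels with at least one in-plane background 4-neighbor,
converted to mm.

## Persistence computation

Cubical persistence uses the **V-construction**: voxels are vertices of the
complex and every higher cell enters at the maximum of its vertices — the
dominant convention for image sublevel persistence. Pairing is computed over
GF(2) by left-to-right boundary-matrix reduction with the twist (clearing)
optimization, processing dimensions top-down; ties in filtration value are
broken by dimension and then by lexicographic cell index, so results are
platform-independent. Zero-persistence pairs are discarded at construction.
Each connected component of the finite support yields one essential
dimension-0 class born at the component minimum. A lesion grid whose mask
encloses a cavity also carries an essential dimension-2 class — the void
never fills because its interior is excluded from the complex. These
essential classes are genuine signal and are counted by the vectorization.

Rips persistence on the surface cloud is *approximated*, as point clouds of
real lesion surfaces are large: clouds above `max_points` are reduced by
farthest-point subsampling (seeded start), and simplices up to dimension 3
with diameter at most the subsample's enclosing radius are enumerated
explicitly. The default budget is 64 points: homology through dimension 2
requires all tetrahedra, and the complex grows as C(n, 4) — 64 points give
~6.4 × 10⁵ cells and run in well under a second, while budgets in the
hundreds would cost gigabytes. The budget and threshold are exposed as
parameters.

A deliberately naive reference path (`naive_cubical_persistence()`,
`naive_rips_persistence()`, built on the exported
`reduce_boundary_matrix()` without clearing, with all cells enumerated in
R) validates the optimized implementation; the test suite checks equality
of diagrams on randomized small grids and clouds, Betti-number consistency
against the labeling auditor, and a perturbation-stability smoke test.

## Vectorization: 15 diagrams, 290 features

For each diagram, 19 statistics are computed over its finite pairs: mean,
population sd (0 for a singleton), min and max of the birth, death,
persistence and midlife series (16 values); the finite and infinite pair
counts; and the persistence entropy H = −Σ pᵢ log pᵢ with pᵢ the normalized
persistences (natural log). A diagram with no finite pairs contributes
counts of 0 and `NA` elsewhere — downstream imputation handles these, which
is exactly why the protocol's preprocessing begins with mean imputation.
Adding the per-object `essential0_birth` (minimum birth among essential
dimension-0 classes; the component-level "appearance intensity") gives
15 × 19 + 5 = 290 named features in a fixed canonical order. The statistic
registry is a single function, so an alternative statistic set can be
swapped without touching the pipeline.

Persistence-based statistics are invariant under global intensity shifts;
birth/death statistics are equivariant — both properties are tested.

## Preprocessing, selection, models, combination

Within every training fold (never on test rows): missing values are imputed
with the feature mean; features are min–max scaled to [0, 1] (test values
clipped; constant features map to 0); scaled features are binned into 5
equal-width partitions. The binned copies feed mRMR — greedy forward
selection of 10 features maximizing MI(f; y) minus the mean MI with the
already-selected set (the MID difference criterion; MIQ available), with
lexicographic tie-breaks for determinism. Continuous outcomes are
discretized into 5 equal-frequency bins for the MI computations only.
Models are trained on the *continuous* scaled copies of the selected
features: binning exists to serve the selection step.

Six families, each in classification/regression variants: logistic/linear
regression, random forest (`ranger`), k-nearest neighbors, support vector
machine (`e1071`), Gaussian naive Bayes / ridge regression with a fixed
Gaussian prior, and gradient-boosted trees (`xgboost`). Hyperparameters are
library defaults with fixed seeds and single-threaded execution, so runs
are bit-reproducible.

Strategies: `rad` and `top` run one block; `concat` pools both blocks
before selection (still 10 features); `vote` averages the two block models'
probabilities; `stack` builds out-of-fold base outputs via an internal
seeded 5-fold split, then fits a final model *of the same family* on them.
When a class is too small for the internal split, the stack records a skip
in the experiment log rather than failing — mirroring situations where a
cohort has too few scans of one histology to evaluate stacking.

## Evaluation protocol

10 repeats of 5-fold cross-validation by default (experiments in this
package's own test suite use 3 × 5 where runtime matters; the vignette
notes the sizes used in each place). Fold assignments are built once per
experiment and shared across all strategies and models. Sampling schemes:
nodule-level stratified; patient-grouped random (a patient's nodules never
straddle folds); and patient-grouped stratified on a patient-level class
indicator. Classification is scored by ROC AUC in its Mann–Whitney form
(ties count ½), regression by r². The mean performance of a cell is the
mean over all fold scores.

**The vote-versus-rad comparison.** The reported p-value tests H₀: mean
radiomic performance ≥ mean voting performance, over matched fold scores.
Fold scores of a repeated CV are positively correlated through the shared
data, and the plain paired t-test is substantially anti-conservative in
this setting (we measure ≈ 0.19 empirical size at α = 0.05 on null data).
The default is therefore the Nadeau–Bengio variance-corrected resampled
t-test, which inflates the variance of the mean difference by
1/J + n_test/n_train; its measured size on 200 null replicates is ≈ 0.05.
The uncorrected t-test and a Wilcoxon signed-rank test remain available as
options.

## Numerical and design choices

* Coefficients in GF(2); homology through dimension 2 only.
* Zero-persistence pairs discarded; diagrams may be empty.
* Equal filtration values are ordered by (value, dimension, cell index).
* `roc_auc` returns `NA` (logged) for single-class test folds; `r_squared`
  returns `NA` for constant truth; single-class *training* folds raise a
  typed condition the CV driver records.
* A constant nonzero score difference makes the paired test degenerate; it
  is reported as a machine-epsilon bound with a `degenerate` flag.
* The null-signal statistical check pools three independent cohorts: the
  CV-mean AUC of a single finite cohort has seed-level sd ≈ 0.04 (feature
  selection on a few hundred features and 80 patients), so a one-cohort
  check against a ±0.05 band would reject a correct, leak-free pipeline
  far too often.

## Known limitations

* The stand-in radiomic block is 21 first-order and shape features, a
  structural placeholder for a full IBSI extractor's output; any external
  radiomic CSV with `rad_`-prefixed columns drops in.
* Rips diagrams are subsample approximations; dimension-1/2 features of
  very fine surface texture are below the default budget's resolution.
* Multi-lesion masks are reduced to the largest connected component, with a
  warning.
* The synthetic cohorts are morphological caricatures; see the generator
  section for what they do not model.

## A minimal session

```{r example, eval = FALSE}
co <- generate_cohort(n_patients = 20, seed = 1)
ft <- extract_features(co)
res <- run_experiment(ft, kinds = "LR",
                      strategies = c("rad", "top", "vote"),
                      repeats = 3, folds = 5,
                      sampling = "grouped_patient_stratified", seed = 1)
res
autoplot(res)
```
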