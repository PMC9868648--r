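# topohist

Benchmarks **persistent-homology (topological) features against radiomic
features for lung nodule histology prediction** from CT-like volumes — for
researchers in quantitative medical imaging who want a tested, reproducible
implementation of the full comparison protocol, runnable end-to-end on
synthetic cohorts.

## What it computes

From each scan (an intensity volume plus a lesion segmentation), after
resampling to 1×1×1 mm, five filtration objects are built:

* the lesion voxels, raw and negated (sublevel filtration of x and of −x),
* the lesion plus its surrounding boundary box, raw and negated,
* a point cloud of the lesion surface (stacked axial contours).

Sublevel **cubical persistence** (V-construction, GF(2), boundary-matrix
reduction with clearing) is computed for the four grids and **Vietoris–Rips
persistence** (farthest-point-subsampled) for the cloud, each in homology
dimensions 0–2: components H₀, loops H₁, voids H₂. That yields 5 × 3 = 15
persistence diagrams per scan — multisets of (birth, death) pairs — which
are vectorized by summary statistics (mean/sd/min/max of birth, death,
persistence d−b and midlife (b+d)/2, pair counts, persistence entropy
H = −Σ pᵢ log pᵢ, and per-object essential-class births) into a fixed
**290-entry feature vector**.

The evaluation protocol mirrors standard radiomics practice: per training
fold, mean imputation → min–max scaling to [0,1] → 5 equal-width bins →
**mRMR** selection of 10 features (greedy MI difference criterion); six
model families (LR, RF, KNN, SV, BAY, XGB, classification and regression
variants); five combination strategies (**rad**, **top**, **concat**,
**vote**, **stack**); repeated stratified or patient-grouped k-fold CV
scored by ROC AUC / r²; and a one-sided paired comparison of vote vs rad
(Nadeau–Bengio corrected resampled t-test by default).

A synthetic-cohort generator plants class-conditional morphology —
lobulation, spiculation, and internal cavities (which appear as essential
H₂ classes) — with auditable Betti numbers, so the whole pipeline is
testable without clinical data. Real feature tables (e.g. an IBSI-compliant
radiomics CSV) drop in wherever the `rad_` block is used.

## A worked example

```r
library(topohist)

co  <- generate_cohort(n_patients = 20, seed = 1)   # 23 nodules (some patients have 2)
ft  <- extract_features(co)                         # 23 x 315: keys + 21 rad_ + 290 top_
res <- run_experiment(ft, kinds = "LR",
                      strategies = c("rad", "top", "vote"),
                      repeats = 3, folds = 5,
                      sampling = "grouped_patient_stratified", seed = 1)
res
#> <cv_result> classification of 'class_label': 3 repeats x 5 folds, grouped_patient_stratified sampling
#>  model  rad top vote
#>     LR 87.8 100 98.3
#> p (vote >= rad): LR 0.2
```

The table prints mean cross-validated ROC AUC in percent per strategy:
radiomic features alone reach 87.8, topological features alone 100 (the
planted cavities are a near-separable H₂ signal), and the soft-voting
ensemble 98.3. The p-value tests H₀ "rad is at least as good as vote" over
matched folds. `tidy(res)` returns per-fold scores, `glance(res)` a
one-row summary, `autoplot(res)` the score boxplots.

Per-scan quantities are just as accessible:

```r
scan <- generate_nodule(nodule_params(base_radius_mm = 9, cavity_count = 1), seed = 5)
ds   <- compute_diagram_set(scan$volume, scan$mask)  # 15 diagrams
fv   <- vectorize_scan(ds)                           # 290 named features
fv["lesion_dim2_n_infinite"]                         # the planted cavity: 1
autoplot(ds)
```

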