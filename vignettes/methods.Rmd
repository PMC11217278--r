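---
title: "Connectivity parcellation and diffusion biomarkers: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity parcellation and diffusion biomarkers: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subparc)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open.

## 1. The analysis model

The pipeline asks whether a diffusion-MRI microstructure metric, measured in
a connectivity-defined *subregion* of a subcortical structure, separates
prodromal (iRBD) and early Parkinson's disease (ePD) patients from healthy
controls (HC) better than the whole-structure average does. Its stages:

**Surfaces.** A structure's probabilistic atlas map $p(\mathbf{x}) \in
[0,1]$ is isosurfaced at a stated intensity. Small midbrain nuclei (VTA,
SNc) are first upsampled to 200 % resolution (trilinear) and isosurfaced at
0.3 with no decimation; the striatum is isosurfaced at 0.5 and decimated by
25 % of vertices. Both recipes are pure configuration in
`extract_surface()`.

**Parcellation.** Streamlines are seeded at every surface vertex (the
seeding protocol the package emulates uses 250 per vertex from 0.5 mm
spheres; `seed_spheres()` records the geometry). With $C[v,t]$ the count of
streamlines from vertex $v$ terminating in cortical target $t$,
winner-take-all voting assigns

$$\mathrm{label}(v) = \begin{cases}\arg\max_t C[v,t] & \max_t C[v,t] \ge m\\
0 \ (\text{unassigned}) & \text{otherwise,}\end{cases}$$

where $m$ is the minimum fibre count that prevents assignment on low
evidence. VTA and SNc vote over four targets (limbic, executive,
rostral-motor, caudal-motor); the striatum over six (plus parietal,
occipital).

**Features.** Per region slot (each subregion and the unparcellated
"total"), four features: *bundle* MD/FA — the unweighted mean of the scalar
map over voxels traversed by streamlines that start in the subregion and
end in its matched target — and *surface* MD/FA — the mean of the map
sampled at the subregion's vertex coordinates. MD is carried in mm²/s
(grey-matter baseline about $0.7\times10^{-3}$), FA is unitless in $[0,1]$.

**Statistics.** Per feature, Levene's test (median-centred, i.e.
Brown–Forsythe) gates the route: below $p < .05$ the feature goes to
Kruskal–Wallis $H$ (tie-corrected) with Dunn $z$ post-hocs, otherwise to an
ANCOVA with Group plus age, sex (and site when it varies). The omnibus
Group test is a nested-model F; effect size is partial eta squared. The
family-wise correction defaults to Bonferroni with family size $m = 96$,
with Benjamini–Hochberg as the liberal alternative. Group *equivalence*
(iRBD vs ePD) is assessed by a Bayesian ANCOVA approximated through BIC:
$\mathrm{BF}_{10} = \exp((\mathrm{BIC}_0 - \mathrm{BIC}_1)/2)$.
Clinical association uses Spearman's rank correlation, exact for $n \le 9$.

**Classification.** A random forest with balanced class weights, trained on
a group-stratified 80 % sample; hyperparameters maximise mean stratified
5-fold CV AUC over a budget of trials (default 100) with an adaptive
TPE-style proposer; the final model is evaluated once on the 20 % hold-out
(ROC/AUC, confusion at 0.5 and at the F1-optimal threshold, balanced
accuracy), and its stability is assessed by refitting on 200 bootstrap
resamples of the training set against the fixed hold-out.

## 2. Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| isosurface threshold | 0.5 (striatum), 0.3 (VTA/SNc) | probability | stated mesh recipe; 0.3 keeps the small nuclei from fragmenting |
| upsampling | 100 % / 200 % | grid resolution | 200 % before isosurfacing the small nuclei |
| decimation | 0.25 / 0 | vertex fraction | stated recipe; quadric edge collapse to an exact count |
| seeds per vertex | 250 | count | stated seeding density |
| seed sphere radius | 0.5 | mm | stated seeding geometry |
| `min_count` | 10 (of 250) | streamlines | the minimum-fibre limit is stated without a number; 4 % of seeds is logged in provenance and configurable |
| tie policy | lowest index | — | deterministic; "unassigned" and seeded-random selectable |
| MD baseline | 0.7e-3 | mm²/s | adult grey matter magnitude |
| FA baseline | 0.25 | — | subcortical grey matter magnitude |
| subject SD | 0.03 | lognormal scale | between-subject microstructure variability |
| voxel SD | 0.01 | multiplicative | map-level measurement noise |
| family size $m$ | 96 | tests | the stated Bonferroni family; always explicit in reports |
| test fraction | 0.20 | — | stated hold-out design; per-class largest-remainder allocation |
| CV folds / trials / bootstraps | 5 / 100 / 200 | — | stated search and stability budgets |

## 3. What the generator emulates — and what it does not

`phantom_spec()` builds a world in which every downstream claim has a known
truth: smooth blobs $p = \exp(-\ln 2\, (d/r)^2)$ (so the 0.5 level sits
exactly at radius $r$) stand in for the probabilistic atlas; six disjoint
cortical patches per hemisphere stand in for the cortical label volume;
geometric 3-point polylines from vertex to a sampled target voxel stand in
for probabilistic tractography; MD/FA fields are baseline times a
multiplicative subregion shift (patients only), a lognormal subject
intercept, and voxel noise; cohorts carry age, sex, site, MoCA, MDS-UPDRS-III
and RBD-questionnaire covariates with group-specific distributions, and the
motor score can be copula-correlated with the latent subject intercept.

Ground truth is a band rule: each blob is split into equal-width bands along
the anterior–posterior axis, one band per cortical target in canonical
order. The same rule paints voxel-level effects and labels vertices, which
closes the loop: with zero noise the pipeline recovers an injected +10 %
shift exactly (the painted band is extended by one voxel so every vertex of
the band samples a fully-shifted trilinear neighbourhood; the price is that
roughly one voxel's width of the *adjacent* band is also shifted — a
partial-volume analogue, visible as a ~4 % spill in the neighbouring
subregion at a 10 % shift).

The generator does **not** emulate: fibre-orientation distributions or
tracking errors (streamlines cannot cross into the wrong hemisphere or stop
mid-way except by the explicit failure probability), scanner artefacts
beyond an additive site offset, spatially correlated noise, or atlas
misregistration. A green test therefore establishes the *computational*
correctness and statistical calibration of the pipeline, not robustness to
real acquisition physics.

Inter-subject MD variability has no stated distributional form; it is taken
lognormal (Gaussian on the log scale), which keeps maps positive and makes
multiplicative shifts act additively on the log scale. This is configurable.

The large calibration suites (500 null families; 100 effect replicates) draw
feature tables from `simulate_feature_table()`, the feature-level statement
of the same model (baseline × subject intercept × feature noise × shift,
with a 1 %/decade age trend), rather than synthesising half a million images.
The closed-loop tests tie the two routes together at zero noise; the
calibration then measures the statistics, not the renderer.

## 4. Numerical choices

* **Isosurfacing** is marching tetrahedra: each cube is split into six
  tetrahedra sharing the main diagonal (a mirror-consistent split, so the
  surface is watertight), with linear interpolation along tet edges. The
  named intensity is honoured exactly; the algorithm itself was unstated,
  and marching tetrahedra avoids the ambiguous cases of cube-based tables.
  Vertices are welded both by edge key and by position (an intersection
  falling exactly on a grid node is reached from several edges). Triangles
  are oriented outward numerically; degenerate faces are dropped. On an
  analytic 8 mm sphere the area converges within 0.3 % at 1 mm voxels and
  every component has Euler characteristic 2.
* **"Resampling by 200 %"** is read as doubling grid resolution (halving
  the voxel size) by trilinear interpolation before isosurfacing.
* **Decimation** is cheapest-edge collapse under per-vertex quadric error
  (midpoint placement), run to exactly $\lceil(1-f)V\rceil$ vertices; area
  is preserved within 10 % at $f = 0.25$ on test meshes.
* **Terminal labelling** uses the final streamline point only (nearest
  voxel under the affine); out-of-grid terminations are background.
* **Surface sampling** is trilinear by default (nearest-neighbour
  selectable); vertices outside the scalar grid are excluded and counted.
* **Bundle voxelisation** marks voxels containing any point of the bundle
  resampled at a tenth of the voxel size — comfortably below the half-voxel
  contract, and agreeing with a dense brute-force sampling oracle.
* **Empty bundles yield nulls, not zeros** — a zero would silently drag
  group means toward zero.
* **Hemispheres** are averaged with vertex-count weights by default
  (separate-column mode available), matching single-value-per-structure
  reporting.
* **Ties** in winner-take-all go to the lowest target index by default —
  deterministic and order-stable under the fixed canonical target
  enumeration.
* **Pairwise ANCOVA contrasts** report $df = n_i + n_j - 2$, matching the
  printed t-statistic convention; the adjusted-model residual df is
  available behind a flag.
* **BF10 by BIC** approximates a JZS-prior Bayesian ANCOVA. Only the
  *direction* (above or below 1) is treated as meaningful; printed JZS
  magnitudes would differ.
* **Exact Spearman p** enumerates all $n!$ rank permutations for $n \le 9$
  (untied data); ties fall back to the t approximation.
* **Seeds.** Every random draw flows from `(master seed, tag)` through a
  32-bit FNV-1a hash (`derive_seed()`): subjects, CV folds, search,
  bootstrap and permutations each own a stream, so enlarging a cohort or
  changing the search budget perturbs nothing else.

## 5. Open design points, resolved

* **Voting unit.** Seeding is per vertex and the features are
  vertex-based, so voting is per *vertex*; a voxel-level aggregation
  (`paint_parcellation()`) exists for mask export.
* **Minimum fibre count.** No value is stated; the default is 10 of 250
  (4 %), recorded in provenance, and the monotonicity property (raising the
  limit only unassigns, never flips) is tested.
* **"Total" regions include unassigned vertices** — the unparcellated
  structure is the natural control measure and its surface is well defined
  whether or not every vertex won a vote. A flag excludes them.
* **Family composition of the 96.** How the stated family decomposes into
  features × regions × datasets is not derivable; $m$ is therefore an
  explicit, reported config value defaulting to 96, and the battery is
  conservative whenever the actual test count is lower (our synthetic grid
  has 68 columns).
* **Construction-then-propagation order** for meshes (decimation happens in
  template space, then vertices are transformed) follows the order in which
  the recipe is stated.
* **Search conformance.** The tuner's contract is "best mean CV AUC within
  the budget, seeded"; the adaptive proposer is a one-dimensional-factorised
  Parzen density-ratio sampler after a random start-up quarter, with pure
  random search as a fallback mode. Any maximiser over the same bounded
  space conforms.
* **Class balancing** uses class weights (inverse-frequency sample weights
  in every Gini computation), not resampling.

## 6. Known limitations

* The random forest is an in-package Rcpp implementation (no forest package
  ships in the target environment). It implements exactly what the
  evaluation needs — Gini CART, bagging, mtry, class weights, impurity
  importances — and nothing more (no OOB estimates, no regression mode).
* NIfTI support covers NIfTI-1, 3-D, sform affines and the common dtypes;
  NIfTI-2, qform-only files and 4-D series are rejected with typed errors.
* TPE here factorises the proposal density over hyperparameters; the
  original algorithm models joint densities. With four dimensions and
  budgets of ~100 this is immaterial to the best-of-budget contract.
* The BIC Bayes factor is a large-sample approximation; equivalence
  conclusions should quote it as such.
* Statistical calibration is demonstrated on the generator's lognormal
  world. Heavy-tailed real data would shift more features onto the
  non-parametric route — by design — but the type-I calibration evidence
  does not extend to arbitrary real-world distributions.
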