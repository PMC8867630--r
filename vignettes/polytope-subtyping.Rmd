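---
title: "Max-margin polytope subtyping: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Max-margin polytope subtyping: models, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysub)
```

## The problem

Case-control comparisons of regional brain volumes average over patients
who may deviate from controls in qualitatively different ways. When one
subgroup shows volume increases and another shows decreases, the group mean
contrast washes out and a single case-control classifier hovers near
chance. `polysub` addresses this by *semi-supervised* subtyping: instead of
clustering patients by mutual similarity (which mixes disease-related and
irrelevant variation), it clusters the ways patients *differ from
controls*.

## The model

Controls are labeled $y_i = +1$, patients $y_i = -1$. A model with $k$
subtypes consists of $k$ linear faces $(w_j, b_j)$ forming a convex
polytope: controls should lie on the positive side of *every* face, and
each patient on the negative side of the face it is assigned to. With
assignment indicators $s_{ij} \in \{0,1\}$, $\sum_j s_{ij} = 1$, the
objective is

$$
\min_{W,b,S} \sum_{j=1}^{k} \frac{\lVert w_j \rVert^2}{2}
 + C \sum_{j=1}^{k} \Big[
 \sum_{i:\,y_i=+1} \tfrac{1}{k}\, \ell_{ij} +
 \sum_{i:\,y_i=-1} s_{ij}\, \ell_{ij} \Big],
 \qquad \ell_{ij} = \max(0,\, 1 - y_i (w_j^\top x_i + b_j)).
$$

Every control carries weight $1/k$ on every face, so the total control
influence is constant across $k$; each face's negative class is its
assigned patients. The decision score of a subject is
$\min_j (w_j^\top x + b_j)$: positive inside the polytope (control-like),
negative outside. The subtype of a patient is the face it is assigned to.

Fitting alternates between a *hyperplane step* — each face is an
$L_2$-regularized weighted hinge-loss (max-margin) problem, solved exactly
in the dual by a compiled SMO solver with per-sample box constraints — and
an *assignment step*.

### The assignment rule

"Assign each patient to the closest hyperplane" admits three readings, all
implemented (`assignment =`):

* `"signed"` (default): $\arg\max_j (w_j^\top x_i + b_j)$, the largest
  (least negative) signed decision value;
* `"distance"`: $\arg\max_j (w_j^\top x_i + b_j)/\lVert w_j \rVert$, the
  Euclidean-closest hyperplane;
* `"hinge"`: $\arg\min_j \ell_{ij}$, the face with the smallest hinge loss.

Only `"hinge"` is exact block-coordinate descent on the objective, and only
under it is the objective guaranteed monotone non-increasing (the property
suite asserts this). Under `"signed"`, two symmetric optima that differ
only by a face permutation form a 2-cycle: the labels alternate while the
*partition* is fixed. This is harmless — every downstream quantity
(stability, consensus, effect maps) is invariant to face relabeling — but
it dictates two implementation details:

* **Convergence** is declared when the patient partition repeats *up to
  relabeling* (canonical relabeling comparison, with a visited-set so
  longer cycles also terminate), not when raw labels freeze.
* **Run scoring** (choosing among restarts, and the best-visited state
  within a run) uses a relabeling-invariant *separation objective* in which
  each patient pays the hinge of its best face. The as-assigned objective
  of a perfect partition caught mid-cycle can exceed that of a degraded
  one, so it cannot rank runs.

### Initialization

Uniformly random hard assignments fail structurally, not just slowly: a
face fitted against a well-mixed patient set admits the degenerate global
optimum $w = 0$, $b = -1$ — every patient sits exactly on the margin at
zero loss, the controls are sacrificed at constant cost, and the patient
subgradients cancel. All faces then coincide, every patient ties, and the
partition collapses. Restarts therefore use *directional prototype
seeding*: $k$ patients are drawn by k-means++-style $D^2$ sampling of
their control-centroid deviations, and every patient starts on the
prototype with the largest projection. This is still uniformly random over
seeds but spatially coherent, and makes one-prototype-per-cluster starts
overwhelmingly likely.

### Optimizer schedule

Each restart runs `burn_in = 3` alternations; the restart with the best
separation objective continues (warm-started) up to `max_iter = 50`, and a
run stops early once its best separation objective has not improved for
`patience = 5` alternations, returning the best-visited state. On
separable data the partition-repeat stop fires within a few alternations
and the schedule changes nothing; on structureless data the signed rule
churns labels indefinitely (we measured 100% label turnover per alternation
with no repeated partition inside 50), and patience caps the wasted work.
Faces are solved to an SMO duality-gap tolerance of $10^{-2}$ by default —
assignments are argmax decisions over faces and insensitive to slack at
that scale; tighten `tol` if raw weights are consumed directly.

Empty faces are re-seeded with the worst-scoring patient so $k$ stays
constant during a sweep.

## Choosing the number of subtypes

`stability_sweep()` wraps the fit in stratified (diagnosis × site) k-fold
cross-validation: for each candidate $k$, the model is fitted on each
training set and every patient collects `folds - 1` labels. Stability is
the mean pairwise adjusted Rand index (ARI) between fold labelings on
shared patients — the stricter of the available conventions — and the
selected $k$ maximizes it, ties resolving to the smaller $k$ (parsimony).
Final labels come from consensus: the co-occurrence matrix (fraction of
shared runs with equal labels) is partitioned spectrally, with the k-means
step repeated `consensus_steps = 20` times under different seeds and the
partition with the highest mean within-cluster co-occurrence kept. A
patient pair never observed together falls back to the mean co-occurrence,
with a warning.

Defaults throughout — $C = 0.25$, 50 alternations, 20 consensus steps, 10
folds, $k \in 2..8$ — follow the conventions of the semi-supervised
subtyping literature this package implements.

## Covariates

Age and site are removed feature-wise by OLS on age plus site indicators
(lexicographically first site as reference). The model is fitted on
controls only by default — regressing on all subjects would absorb disease
effect into the site/age estimates — and applied to everyone; this is a
configurable choice (`fitting_subset`), not an identity, and which subset
the reference analyses used is genuinely ambiguous. In leave-one-site-out
validation the held-out site has no estimable offset; site offsets are
grand-mean-centered and the unseen site receives the zero (average)
offset.

## Reproducibility harnesses

* `split_half()` draws diagnosis × site-stratified halves and redraws (up
  to a bounded budget) until a two-sample t-test on age between halves has
  p > 0.05, then each half runs the full pipeline independently. Subtypes
  are matched *across disjoint subject sets* through their per-feature
  Cohen's d maps versus their own controls (exhaustive permutation
  matching on column correlations), and compared by effect-direction
  agreement over the features FDR-significant in either half — effect maps
  are compared after significance masking, because features carrying no
  effect would contribute coin-flip signs and cap the expected agreement at
  the affected-feature fraction plus half the remainder.
* `leave_one_site_out()` refits covariates and polytope without each site,
  assigns the held-out patients, and reports the percentage that agree
  with the full-sample consensus after optimal label matching — matching
  absorbs global relabeling, so overlap is permutation-invariant.

## Subtype statistics

`subtype_report()` reproduces the standard clinical table: pairwise pooled
two-sample t-tests (subtype1 vs subtype2, controls vs each subtype),
chi-square on the subtype × site contingency table, per-subtype Pearson
correlations of total intracranial volume (the row sum of all features, by
construction) with each score, and per-feature Cohen's d maps versus
controls with Benjamini–Hochberg control at q = 0.05. Voxel-level mapping
and random-field corrections are out of scope; inference is at the ROI
(feature) level. Student's pooled t is the default (Welch behind a flag);
missing clinical values are dropped pairwise per test.

## Dynamic measures

For parcel × time series, four windowed measures are computed per sliding
window (length 30, step 5 timepoints by default — these defaults are this
package's choice, documented rather than inherited): ReHo (Kendall's W of
a parcel with its neighbor set; neighborhoods are the `k = 6` nearest
parcels by full-series correlation, since voxel cubes do not exist at
parcel scale), DC (count of other parcels with window correlation above
r = 0.25), GSCorr (correlation with the mean course), and VMHC
(correlation of explicitly supplied homotopic pairs — the symmetric
registration step of voxel pipelines becomes a data requirement here).
Temporal SD maps summarize each measure across windows; volume-wise
concordance is Kendall's W across the four measures per window (null level
$1/4$), summarized by its temporal mean and SD; functional-architecture
stability is W of a parcel's window-wise connectivity profile across atlas
groups (null level 1/n_windows). Group comparisons residualize age, site
and mean framewise displacement first and correct with BH-FDR. Subjects
exceeding 2 mm translation or 2° rotation are excluded beforehand
(missing motion metadata excludes with a warning).

## Classification

`subtype_aware_evaluation()` quantifies whether subtyping sharpens
case-control separability: balanced subsampling of the majority class
(10 repeats), nested 10 × 10 cross-validated linear SVMs (cost grid
0.01–100, inner ties to the stronger regularization, standardization
learned inside each training fold, no feature selection), accuracy in
percent, and mean absolute weights as feature importance. Under
opposite-direction subtypes the pooled patients-vs-controls accuracy sits
near chance while per-subtype accuracies are far higher; under a single
planted direction the gain vanishes — the package's diagnostic for genuine
heterogeneity. The linear SVMs here are standard components (libsvm via
e1071); the weighted-hinge solver inside the polytope fit is this
package's own, and the two agree at $k = 1$ to $10^{-6}$ (tested).

## What the generator emulates — and what it does not

`simulate_cohort()` plants: site offsets (SD 30 on a residual SD of 100 —
i.e. 0.3 σ), a linear age slope (−5 volume units/year over ages 8–45),
two equal patient subtypes with opposite shifts of d = 0.8 σ on 60% of 142
features, clinical scores with subtype-dependent means (IQ, ADOS, ADI-R,
SRS at the magnitudes of the multi-site autism cohorts this design
mirrors) and target TIV correlations induced by a shared latent factor,
and per-score missingness. `simulate_timeseries()` plants homotopic
coupling and a window-scale modulation of global coupling whose mean is
higher and variance lower in subtype 1 — yielding higher mean / lower SD
of concordance and lower temporal SD for subtype 1. ROI volumes are
Gaussian; this is an assumption, not an inference from data.

Real cohorts add what the generator deliberately omits: non-Gaussian and
heteroscedastic volumes, site-by-age interactions, scanner drift,
diagnosis-dependent motion, unequal subtype prevalence, and registration
error. Passing tests therefore demonstrate *internal correctness and
recoverability under the stated model*, not performance on any real
dataset.

## Numerical choices and degenerate inputs

* Ties in every argmax (assignment, selected k, inner-CV cost) break
  deterministically toward the lowest index / smaller value.
* All randomness flows from explicit `seed` arguments through named
  substreams; reruns are bit-identical (the pipeline's timing log aside).
* Zero-variance features standardize with scale 1 instead of dividing by
  zero; constant features receive (numerically) zero weight.
* Degenerate statistics fail loudly: zero pooled SD with unequal means,
  all-tied raters in Kendall's W, single-class fits, unseen site levels.
* Problem sizes in the test suite: cohorts of 100 + 100 subjects with 142
  features for end-to-end properties (seconds per sweep), 40–80 subjects
  for module tests, 1000-replicate nulls for calibration checks.

## Known limitations

* Faces are linear; nonlinear subtype boundaries are out of scope.
* Assignments are hard; no posterior over subtypes is produced.
* The consensus partitioner assumes the co-occurrence matrix is
  informative; with fewer than ~5 runs it degenerates gracefully but
  noisily.
* Stability-based selection of k inherits the known conservatism of
  pairwise ARI: strongly nested substructure can keep several k values
  near-equally stable, and the parsimony tie-break then favors the
  smallest.
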