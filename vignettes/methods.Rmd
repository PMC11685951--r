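---
title: "Methods: bioavailable Sr isoscapes and isotope-based assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioavailable Sr isoscapes and isotope-based assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Bioavailable strontium isotope ratios (⁸⁷Sr/⁸⁶Sr) vary across landscapes
mainly with bedrock geology: old, rubidium-rich rocks (Archaean cratons)
accumulate radiogenic ⁸⁷Sr and yield high ratios, young volcanics low ones,
with atmospheric deposition (dust, sea salt), soils and climate modulating
what actually enters food webs. Because body tissues record the bioavailable
ratio of the place where they formed, a gridded prediction of ⁸⁷Sr/⁸⁶Sr — an
*isoscape* — lets archaeologists, ecologists and forensic scientists invert a
tissue measurement into a map of plausible geographic origins.

`srisoscape` implements that workflow end to end: regression from
georeferenced point samples onto gridded environmental predictors,
cell-level prediction uncertainty, masking of regions where the model would
extrapolate, residual diagnostics, and continuous-surface assignment of
individuals from one or two isotope systems.

## The prediction model

The isoscape mean surface comes from a bagged regression-tree ensemble
(random forest), `srforest()`. Each of *B* trees is grown on a bootstrap
resample (with replacement, *n* draws of *n*; the in-bag count matrix
*N<sub>b,i</sub>* is retained), and the cell prediction is the tree average
μ(x) = B⁻¹ Σ<sub>b</sub> t<sub>b</sub>(x). Defaults follow the tuning used
for continental Sr isoscapes: `mtry = 2` predictors tried per split and a
minimal terminal-node size of 2, with 500 trees. "Node size 2" is the
operative meaning of the node-size hyperparameter in the tree growers used
by this literature; both values are exposed and `tune_srforest()` refits
over a grid, choosing the out-of-bag (OOB) RMSE minimiser with ties broken
toward the smaller `mtry`, then the smaller node size.

Categorical predictors (lithology classes and the like) are one-hot
encoded. This keeps the tree grower's input purely numeric and, more
importantly, makes the extrapolation rule explicit: a category code never
seen in training cannot be encoded and the prediction is withheld rather
than silently guessed.

Model skill is reported three ways, all computed by the package: OOB R² and
RMSE (averaging, for each training sample, only trees in which it was out
of bag), repeated random k-fold cross-validation (default 5 folds, 10
repetitions, reshuffled per repeat with seeds derived from the run seed; no
spatial blocking, matching common practice for these models), and a
validation holdout of 20 samples drawn uniformly with the run seed before
tuning. Samples falling in the same grid cell are deliberately *not*
aggregated: co-located samples differ through real within-cell variability,
and aggregation would shrink the effective sample size.

## Prediction uncertainty

Cell standard errors use the infinitesimal jackknife for bagging. With
per-tree predictions t<sub>b</sub>(x) and in-bag counts N<sub>b,i</sub>,

  V̂(x) = Σ<sub>i</sub> Cov<sub>b</sub>[N<sub>b,i</sub>, t<sub>b</sub>(x)]²
  − (n/B²) Σ<sub>b</sub> (t<sub>b</sub>(x) − t̄(x))²,

where the covariance over trees uses the population (1/B) normalisation and
the second term is the finite-B bias correction. The correction can
overshoot for small ensembles, so variances are truncated at zero and
truncation events are counted (`n_truncated`). The bias correction is on by
default and exposed as a flag. The implementation is a vectorised
matrix-product form; the test suite pins it against a literal double-loop
evaluation of the covariance formula to 10⁻¹².

The jackknife SE measures bootstrap sampling variability of the ensemble at
a fixed cell. It does not include ensemble bias or within-cell natural
variability; consumers that need a full predictive spread should combine it
in quadrature with a measurement or within-cell term (`extra_sd` in the
assignment functions).

## Extrapolation masking and environmental similarity

Tree averages cannot extrapolate, so cells whose predictor vector leaves
the training envelope are removed. `strict_mask()` masks a cell when any
continuous predictor falls below the training minimum or above the maximum,
or a categorical code is unseen; masked cells become nodata in the
published mean and SE surfaces. As a graded complement,
`mop_similarity()` reports the mobility-oriented-parity environmental
similarity: the mean Mahalanobis distance from each cell's predictor vector
to the nearest 10% (⌈0.1·n⌉ reference points) of the training cloud,
computed with the training covariance. Mahalanobis distance is
affine-invariant, so raw versus standardised predictors is immaterial while
the covariance is full rank; when one-hot columns make it ill-conditioned
(condition number above 10⁸) the covariance is shrunk toward its diagonal
with the smallest shrinkage weight that restores invertibility, and
constant columns are dropped.

## Residual and structure diagnostics

`residual_summary()` reports OOB residuals and the share within ±0.002 (a
conventional reporting band in ⁸⁷Sr/⁸⁶Sr units). `correlogram()` checks the
independence assumption on residuals: great-circle pair distances are
binned into equal-count bins, each bin gets a Moran-style correlation
(mean centred cross-product over pairs divided by the residual variance),
and a null envelope comes from permuting residuals over locations
(2.5/97.5 percentiles of 199 permutations by default). This replaces the
spline correlograms sometimes used for the same question with a fully
specified, testable permutation procedure carrying the same decision
content: is short-range residual autocorrelation present? Bins with fewer
than 30 pairs are flagged as unstable. `importance_permutation()` measures
the OOB MSE increase when one predictor (one-hot groups together) is
permuted, averaged over repeats with a fixed seed, and
`partial_dependence()` traces the mean prediction as one predictor is swept
over its training range (out-of-range values are computed but flagged).

## Assignment of individuals

`likelihood_surface()` turns a tissue value *y* into a per-cell likelihood
using the Normal density with mean μ<sub>c</sub> and SD
√(σ<sub>c</sub>² + extra_sd²); masked cells get likelihood zero.
`posterior_surface()` multiplies in an optional region prior (e.g. a binary
mask encoding ancestry evidence), renormalises to sum to one, and also
returns the display surface divided by its maximum — the standard
presentation for maps of relative origin probability. For dual-isotope
assignment the raw component likelihoods are multiplied and normalised
once; the per-isotope components are retained. Multiplication commutes, so
the component order is immaterial.

Tooth-enamel carbonate δ¹⁸O (VPDB) is converted to drinking-water δ¹⁸O
(VSMOW) through the standard three-stage affine chain: 1.03091·x + 30.91
(VPDB→VSMOW), 0.98·x − 8.5 (carbonate→phosphate), 1.54·x − 33.72
(phosphate→water). The chain composes to slope 1.555849…, intercept
−0.160628…, which the tests verify symbolically, and the simulator uses the
exact inverse. The default `o_extra_sd = 1` ‰ absorbs the regression error
of these conversions and is combined in quadrature with the δ¹⁸O isoscape
SE; quadrature is the natural choice for independent error sources. For
strontium the default `extra_sd` is 0 — assignment practice typically
trusts the isoscape SE — but a measurement or within-cell SD can be
supplied.

Two credible-region utilities are provided, and the distinction matters.
`top_fraction_region(result, q)` is the smallest set of cells holding
posterior **mass** q (ties by row-major index). For a correctly specified
posterior the true origin falls inside a q-mass highest-density region with
probability exactly q — that is what calibration means — so mass-based
regions are statements about the posterior, not skill scores.
`top_area_region(result, f)` instead keeps the top fraction *f* of cells by
posterior rank; the frequency with which the true origin lands in a small
top-area region is the standard quality-assessment curve for isotope
assignment and does reward sharp, well-ordered posteriors. The synthetic
recovery experiment below reports both.

## The synthetic-data generator

`make_landscape()` builds the study conditions every stage is tested
against: a 200 × 200 lon/lat grid (0.05° cells), eight Voronoi "terrane"
blocks with random ages, per-block Sr means rising monotonically with age
across 0.705–0.735, a dust field subtracting up to ~0.003·(standardised
dust), small-scale smooth noise (0.0015), and clipping to the plausible
bioavailable range [0.703, 0.88]. Covariates are the age layer, three
standardised smooth Gaussian fields (dust, precipitation, elevation — the
latter two pure distractors) and a categorical lithology layer derived from
the blocks. Sampling (`sample_sites()`, default 800 sites) is uniform over
cells with duplicates allowed and adds Normal within-cell noise (SD 0.002,
a realistic within-cell spread for mixed plant/soil/fauna sampling);
individuals (`simulate_individuals()`, default 100) draw a uniform origin
cell, tissue Sr with the same noise, and optionally a δ¹⁸O value pushed
backwards through the conversion chain. All draws flow from one root seed.

What the generator does *not* emulate: real predictor distributions or
their mutual correlations, anisotropic geology, spatially clustered
sampling effort, inter-laboratory offsets, and within-cell noise that
varies by sample type. Passing the recovery tests therefore shows the
machinery is correct and the workflow can recover a truth of this
structure; it does not certify accuracy on any real landscape.

At these study sizes (40,000 cells, 800 samples, 500 trees, 100
individuals) a full simulate–build–assign cycle, including repeated
cross-validation, runs in well under a minute on one CPU; these sizes were
chosen so the whole suite iterates quickly while keeping the
cells-per-sample ratio severe enough to be informative.

In the default experiment the holdout R² is ≈ 0.9 and the top-20%
**area** region contains the true origin for roughly four out of five
individuals, while the top-20% **mass** region contains it for roughly one
in five — numerically confirming the calibration identity above rather
than indicating a defect.

## Numerical and design choices

- **Rasters.** Grids are written as ESRI ASCII (`.asc`) with a `%.17g`
  payload, so doubles round-trip bit-exactly, plus a JSON sidecar for CRS
  and layer kind. Cells are addressed row-major from the north-west corner;
  points are assigned by half-open intervals with west/north edges
  inclusive, so boundary points belong to exactly one cell.
- **Infilling.** A sample whose cell lacks a predictor value takes the
  nearest non-missing cell's value (categorical) or the mean of the five
  nearest (continuous), distances between cell centres (great-circle on
  lon/lat grids, Euclidean on projected ones), ties broken by row-major
  cell index; donors beyond `max_radius` make the infill fail loudly. Every
  infill is logged.
- **Collinearity screen.** Pearson correlations and VIFs over continuous
  columns only; rank-deficient designs report infinite VIF instead of
  erroring. The screen is advisory — predictor selection is configuration,
  not automation. The default flag threshold is |r| > 0.8.
- **Determinism.** One run seed feeds the fit, the CV reshuffles
  (`seed + 1000·repeat`), the holdout draw, the permutation diagnostics and
  the generator; a rebuild with the same inputs and seed is artifact-
  identical (the pipeline stamps a config hash into `run_info.json`).
- **Degenerate inputs.** Constant responses give zero RMSE everywhere and
  deterministic tie-breaks; a constant ensemble gives zero jackknife
  variance; identical residuals give NA correlogram bins; an all-zero
  likelihood (prior excludes all support) is an explicit error.

## Limitations

The spatial cross-validation debate is sidestepped deliberately: folds are
random, so CV measures interpolation skill under the training
distribution, not transferability. The jackknife SE understates full
predictive uncertainty (see above). Masking guarantees no strict
extrapolation but similarity-based caution (MOP) remains advisory. The
assignment model assumes Normal errors and independence between isotope
systems given location.
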