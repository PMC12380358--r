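---
title: "Methods: EEM origin tracing with ATLD and chemometric classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEM origin tracing with ATLD and chemometric classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

An excitation–emission matrix (EEM) records fluorescence intensity over a
lattice of excitation wavelengths (here 200–375 nm) and emission wavelengths
(270–550 nm), both at a 5 nm step. For a dilute mixture of N fluorophores,
stacking I samples gives a three-way array that is *trilinear*:

$$x_{ijk} \;=\; \sum_{n=1}^{N} c_{in}\, b_{jn}\, e_{kn} \;+\;
\varepsilon_{ijk},$$

where $b_{\cdot n}$ and $e_{\cdot n}$ are the emission and excitation
profiles of fluorophore $n$ and $c_{in}$ its relative amount in sample $i$.
Under mild conditions this decomposition is unique up to permutation and
scale — the "second-order advantage" — so the fitted $c_{in}$ are chemically
meaningful per-sample features even in the presence of uncalibrated
interferents. The pipeline's assumptions are therefore: additive
contributions (dilute solutions, no inner-filter effect), profiles shared
across samples (one instrument, one solvent), and scatter removed before
fitting (Rayleigh/Raman ridges violate trilinearity).

## Preprocessing

Scatter is excised per excitation column with banded interpolation
(`scatter_params()`):

* first-order Rayleigh, band $|\lambda_{em} - \lambda_{ex}| \le 35/2$ nm;
* second-order Rayleigh, $|\lambda_{em} - 2\lambda_{ex}| \le 5/2$ nm;
* solvent Raman at $\lambda_{raman} = 1/(1/\lambda_{ex} - s\cdot 10^{-7})$
  nm with shift $s = 3382\ \mathrm{cm}^{-1}$ (water OH stretch; the shift is
  configurable), band $\pm 5/2$ nm.

Band widths are interpreted as *total* widths, the common convention in EEM
correction. Flagged runs interior to the emission axis are bridged by a
natural cubic spline fitted to the unflagged cells of the same column;
interpolation runs along emission because that is the instrument's scan
axis, so scatter runs are contiguous there. Runs touching the
short-wavelength end of the axis lie at or below the first-order Rayleigh
line — the anti-Stokes region carries no fluorescence — and are set to zero
by default (`below_rayleigh_policy`); runs touching the long-wavelength end
extend the nearest unflagged value, since one-sided spline extrapolation is
unstable. Unflagged cells are never altered.

Blank handling averages the (three, by default) blank EEMs cell-wise and
subtracts the average from every sample *after* cropping and *before*
interpolation, so reproducible blank structure (the solvent Raman band) is
subtracted rather than interpolated, and only the residual scatter is
bridged. Negative residuals are retained; `clip_negative()` is available but
off by default.

## ATLD

`atld_fit()` implements the classic alternating scheme built from truncated
Moore–Penrose pseudoinverses. With sample slices
$X_i = B\,\mathrm{diag}(c_i)\,E^{\mathsf T}$, the updates are

$$c_i \leftarrow \mathrm{diag}\!\left(B^{+} X_i (E^{\mathsf T})^{+}\right),$$

with symmetric updates for $B$ (from emission-mode slices) and $E$
(excitation-mode slices); pseudoinverses are truncated at rank N (the
`pinv_truncation` default — the truncation rank is not dictated by the
method, so it is exposed). This scheme converges in a handful of sweeps on
EEM-like data and, when N is overestimated, parks the surplus components at
near-zero intensity instead of destabilising the genuine ones; both
properties are asserted in the test suite.

Numerical choices:

* **Initialization** — singular vectors of the two non-sample unfoldings
  (deterministic); random initialization with a mandatory seed is retained
  for multi-start identifiability checks.
* **Convergence** — stop when the change in residual sum of squares between
  sweeps falls below `tol` ($10^{-6}$) *relative to the total sum of squares
  of the tensor*. Normalising by the current loss instead would never
  trigger on noiseless data, where the loss itself decays to zero.
* **Identification** — loading columns are scaled to unit norm (all scale
  moves into the scores), each column's largest-magnitude entry is made
  positive, and components are ordered by their contribution to explained
  variance. Nonnegativity is *not* enforced: the unconstrained decomposition
  is the method being implemented, and clean recovery without the constraint
  is itself evidence that the model fits.

## Choosing the component number

`corcondia()` computes the least-squares Tucker3 core implied by the fitted
loadings, $G = X \times_1 A^{+} \times_2 B^{+} \times_3 E^{+}$, and the
consistency $100\,(1 - \|G - T\|_F^2 / \|T\|_F^2)$ against the
superidentity $T$. A value near 100 means the data support a trilinear
model with that many components; the acceptance threshold is 60 %.

`scan_components()` evaluates the diagnostic over a candidate range
(default 1–8). Two design points matter here:

* **Candidate fits use least squares, not ATLD.** The diagnostic is defined
  on least-squares fits: their normal equations become near-singular when N
  is overestimated, the surplus components blow up, and the core collapses
  (to large negative values) — that is what makes the threshold selective.
  ATLD's overfactoring tolerance, a virtue when decomposing, keeps its
  overfactored cores benign and would defeat the rule. The scan therefore
  fits candidates with `parafac_als()` (exact solves, deterministic SVD
  start, tolerance $10^{-9}$, generous iteration cap because ALS crosses
  low-progress plateaus before resolving), selects N, and the pipeline then
  decomposes with ATLD at that N.
* **Selection is the largest N in the initial contiguous run of candidates
  at or above 60 %** — i.e. N is increased until the consistency first
  drops below threshold. An isolated re-ascent past the drop reflects a
  fortuitously benign overfactored solution, not restored trilinearity.
  If even the best candidate explains less than half the variance the scan
  degenerates to the smallest candidate with a warning: the trilinearity
  diagnostic is meaningless for a model that does not describe the data.

## Classification

All classifiers consume the ATLD score matrix — the only per-sample
quantity the decomposition yields — autoscaled (mean 0, unit variance per
component) inside each training fold; scaling parameters are estimated on
training folds only and applied to held-out samples, so no information
leaks. A permutation test (label shuffling drives cross-validated accuracy
to chance) guards this property in the test suite.

* **kNN** — Euclidean distance, k = 3 by default (with six samples per
  class, larger k degenerates), ties broken by the single nearest
  neighbour. The neighbour report lists the seven nearest training samples
  with ids and distances in increasing order; seven is a report format, not
  the vote count.
* **Random forest** — 500 trees, `ceiling(sqrt(p))` features per split,
  Gini impurity, mandatory seed (via the `randomForest` package).
  Importances are normalized mean impurity decreases.
* **PLS-DA** — NIPALS PLS2 against one-vs-all class indicators; prediction
  is the argmax of the fitted indicators. A rejection threshold on the
  largest indicator is exposed (off by default) to reproduce reject-rate
  columns. The latent-variable count is chosen by cross-validation with a
  one-standard-error parsimony rule: the smallest LV count whose accuracy
  is within one SE of the best.
* **Cross-validation** — leave-one-out by default (matching a design whose
  cross-verification set contains all 42 samples); stratified k-fold is
  available and falls back to LOO, with a warning, when a class has a
  single member.

Reports carry the confusion matrix plus per-class sensitivity
($TP/(TP+FN)$), one-vs-rest specificity ($TN/(TN+FP)$), reject rate
(fraction unassigned) and false-recognition rate (fraction assigned to a
wrong class), with a totals row.

## The synthetic generator

`simulate_dataset()` emulates the study conditions so the whole pipeline is
testable without instrument data: 7 origins × 6 replicates, 4
external-validation samples drawn from four of the origins, 3 blanks, and 5
fluorophores with Gaussian excitation/emission bands on the acquisition
lattice. Ground truth (profiles, concentrations, clean EEMs) is retained
for every test.

Key design choices, fixed once:

* **Fluorophores.** Gaussian bands are the minimal model for the smooth
  unimodal profiles the decomposition recovers. Centres sit on jittered,
  evenly spaced slots with guaranteed spacing (20 nm excitation, 30 nm
  emission) so loading matrices stay well conditioned, and the Stokes shift
  is at least 90 nm — typical of plant polyphenol fluorescence — which
  keeps emission bands clear of the first-order Rayleigh region.
* **Group structure.** Four components carry the between-group signal:
  group means sit on a fixed skeleton of exposed convex-hull vertices in
  four dimensions (no group mean lies between two others, which would mask
  a "middle" class for linear indicator classifiers). The two PV-species
  origins share a high level on the strongest dimension (one-sided species
  margin) and differ from each other only along the weakest dimension, so
  resolving all seven origins genuinely needs four latent dimensions. The
  skeleton is scaled so the minimum pairwise group separation is 12
  within-group standard deviations (`separation_level()`, linear in
  `between_group_scale`).
* **The fifth component** is concentration-coupled to the others with
  near-constant level across groups — a fluorophore tracking the shared
  metabolic pool rather than origin. This gives the score matrix an
  effectively four-dimensional autoscaled structure (the origin of the
  "four principal components explain essentially all variance" behaviour)
  while leaving enough independent variation (1.5 % jitter) for the
  five-component trilinear model to remain numerically identified.
* **Within-group variation** uses lognormal draws applied at constant
  absolute scale (sd = 10 % of the baseline concentration per component).
  Purely multiplicative noise would make each group's spread proportional
  to its mean, so high-concentration groups would have two to three times
  the nominal spread and the calibrated separation would overstate their
  effective separation.
* **Scatter and noise.** Ridges along the Rayleigh and Raman lines have
  cross-section sigmas of 5, 1.2 and 1.2 nm — deliberately narrower than
  the removal bands, so at least 99 % of each ridge's squared energy is
  maskable and ridge tails stay off the spline anchor cells; misfit then
  measures algorithm quality, not generator unfairness. Ridge amplitudes
  (1.0, 0.3, 0.2 of peak clean intensity) vary per sample by 10 % so blank
  subtraction leaves realistic residual scatter. Additive Gaussian noise
  defaults to 1 % of the peak clean intensity.

What the generator does **not** emulate: inner-filter and quenching
nonlinearity, instrument drift, wavelength-dependent detector response, and
correlated (non-iid) noise. Passing tests therefore demonstrate that the
pipeline recovers the structure the trilinear model assumes — not that real
spectra satisfy those assumptions.

## Problem sizes and runtime

The test suite and the acceptance script run the full design (46 samples +
3 blanks on the 57 × 36 lattice), a component scan over N = 1–8,
leave-one-out cross-validation for the three classifiers, and a
199-permutation negative control; unit tests use a coarser lattice. The
whole suite completes in about a minute on one CPU, the acceptance script
in well under a minute.

## Known limitations

* The scan refits a least-squares model per candidate N; for much larger
  tensors a randomized or compressed diagnostic would be preferable.
* The spline bridges scatter bands per column independently; structured
  residuals spanning many columns (e.g. a drifting baseline) are out of
  scope.
* Quantitative calibration against analyte standards is not implemented —
  scores are relative intensities, not concentrations in physical units.
* With six replicates per class, leave-one-out estimates of per-class rates
  are coarse (steps of 1/6); the reported 100 % figures should be read as
  "no errors observed at this design size".
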