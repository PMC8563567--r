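---
title: "Dynamic functional connectivity states: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package computes

`dfcstates` analyses per-subject network time courses — a T × N matrix per
subject, one column per resting-state network or region, sampled every TR
seconds — with two complementary views of time-varying connectivity and one
static view:

1. **Tapered sliding-window connectivity.** A rectangular window of L TRs
   (default 22, about 44 s at TR ≈ 2.072 s) is convolved with a Gaussian of
   sigma 3 TR and stepped by 1 TR, giving `floor((T − L)/step) + 1` windows
   (269 for T = 290). Within each window a taper-weighted covariance is
   regularised by the graphical LASSO — maximising
   `log det Θ − tr(SΘ) − λ Σ_{i≠j} |Θ_ij|` — the implied covariance
   `Θ⁻¹` is converted to correlations and Fisher-z transformed. The L1
   weight λ is chosen per subject by 20-fold cross-validation of the
   held-out Gaussian log-likelihood over windows. Edge-wise standard
   deviations across windows summarise connectivity variability.
2. **Brain states.** Vectorised upper-triangle window patterns from all
   subjects are pooled and clustered by k-means under the Manhattan (L1)
   distance with coordinate-wise *median* centroid updates (the L1-optimal
   location), 500 random restarts by default. The number of states k is
   chosen by the elbow of the validity index (within-cluster distance over
   between-cluster distance) across k = 2..6. Four per-subject metrics
   follow: state frequency, mean dwell time, number of transitions, and
   mean intertransition time.
3. **LEiDA (window-free).** Instantaneous phases from the Hilbert transform
   give a phase-coherence matrix `dFC(n,p,t) = cos(θ_n(t) − θ_p(t))` per
   timepoint; its leading eigenvector V1(t) summarises the dominant
   coherence pattern; the time-by-time cosine-similarity (FCD) matrix and
   k-means on pooled eigenvectors yield the same four state metrics plus a
   per-subject mean FCD similarity.
4. **Static netmats.** Full and (ridge-regularised) partial correlations on
   the Fisher-z scale, compared between groups with a Freedman–Lane
   max-statistic permutation test controlling family-wise error across
   edges, both correlation types, and all six signed pairwise contrasts.

Nonparametric group statistics (Kruskal–Wallis, Mann–Whitney U with exact
enumeration for small samples, and a rank-transform permutation MANOVA
using the Pillai trace) compare these measures between groups.

## The synthetic cohort generator

No suitable public multi-subject dataset accompanies this kind of clinical
dynamic-connectivity analysis, so the package ships a generative model used
by every downstream test:

- a first-order **Markov chain at TR resolution** selects a hidden
  connectivity state per volume (so planted dwell times are exactly
  geometric with mean `1/(1 − stay-probability)`);
- given the state, the N-vector is drawn from a zero-mean multivariate
  Gaussian with that state's covariance, plus i.i.d. observation noise;
- group effects enter as per-group overrides of the transition matrix or
  the covariances;
- an oscillatory variant generates sinusoids in the 0.01–0.1 Hz band whose
  phase offsets shrink toward zero with state-dependent coupling, providing
  exact phase ground truth for the LEiDA pathway.

Defaults, chosen once as a realistic desk-scale stand-in: T = 290 volumes,
TR = 2.072 s, three states (one globally sparse; two with a block of
within-block correlation 0.7 anticorrelated −0.25 with the rest — the
segregated-system patterns dynamic studies typically report),
stay-probability 0.95 (mean dwell 20 TR ≈ 41 s, comparable to the window
length), observation noise SD 0.5 on unit-variance signals, ages uniform on
[65, 85], sexes Bernoulli(0.5). These choices mirror the acquisition scale
and cohort shape of elderly clinical resting-state studies without copying
any patient data.

What the generator does **not** emulate: haemodynamic autocorrelation and
convolution, head motion, physiological noise, scanner drift (beyond what
detrending removes), or spatial map misestimation. Passing tests therefore
demonstrate that the pipeline recovers planted covariance/phase structure
under idealised sampling — not that it would detect clinical effects in
real BOLD data.

## Numerical and design choices

- **Taper**: normalised to sum 1 and cropped symmetrically to length L
  about the convolution peak, keeping windowed covariances scale-free. The
  taper weights act as observation weights in the covariance (not as a
  multiplier of the signal), a declared convention.
- **Graphical LASSO**: block coordinate descent with an unpenalised
  diagonal (the standard convention preserving positive-definiteness);
  convergence when the working covariance changes by less than `1e-6`;
  λ = 0 short-circuits to the direct inverse and a singular input suggests
  λ > 0. Correctness is checked against the KKT stationarity conditions
  rather than against another implementation.
- **Cross-validation folds are contiguous blocks of windows**, because
  windows overlapping in time are strongly dependent and random folds would
  leak. Ties in the held-out score break toward the larger (sparser) λ.
  The default grid is 20 log-spaced values in `[1e-3, 1]`.
- **k-means**: restarts draw k distinct data rows as initial centroids; an
  emptied cluster is re-seeded with the farthest point; iteration stops on
  label stability or a relative objective plateau of `1e-7`; the objective
  is non-increasing by construction and asserted in tests. Clusters are
  reported in descending frequency order. With exactly duplicated patterns
  (e.g. perfect synchrony) the validity index is undefined (coincident
  centroids) and reported as `NA` with a warning; elbow selection then
  refuses to pick a k, which is the correct answer for structureless input.
- **Elbow**: the interior k maximising the discrete second difference of
  the validity index; ties (within numerical noise) break toward smaller k.
- **Dwell times include boundary-censored first/last runs** by default
  (with 269 windows, excluding them discards substantial data); the
  convention is switchable via `include_censored = FALSE`. A transition
  sits at the 1-based first window of each new run; intertransition gaps
  are differences of consecutive transition positions, undefined (NA) with
  fewer than two transitions.
- **LEiDA sign convention**: eigenvectors are sign-ambiguous, so V1 is
  flipped to make the majority of components negative (first nonzero
  component negative on exact balance); a degenerate leading eigenvalue
  triggers a warning and a deterministic lexicographic tie-break. Columns
  are mean-centered before the Hilbert transform and one volume is dropped
  at each end (`drop_edges = 1`) against edge artefacts.
- **Despiking** is defined as running-median (window 11) + MAD thresholding
  at 5 robust SDs with natural-cubic-spline interpolation of flagged
  samples. This is a self-contained reformulation of the usual
  curve-fit despiking tools, chosen for testability; when the running
  median reproduces a smooth signal exactly (zero MAD) the scale falls back
  to the nonzero residuals.
- **Residualisation** of edge values on age and sex keeps the grand mean,
  so values stay on the Fisher-z scale; group membership is deliberately
  excluded from that model.
- **Partial correlations** use a ridge of `0.1 · mean(diag(S))` when
  T < 5N, else none — short series need the stabilisation, long ones do
  not.
- **Permutation inference**: Freedman–Lane residual permutation under the
  nuisance (age, sex) model; the observed labelling is one of the
  permutations, so p-values are never 0 and never smaller than
  `1/n_permutations`. The MANOVA is a rank-transform Pillai-trace
  permutation procedure — a methodological substitution for the various
  published nonparametric MANOVA variants, not a reimplementation of any
  specific one; compositional responses (frequencies summing to 1) are
  reduced to a full-rank column basis first.
- **Indices** are 1-based and inclusive everywhere in files and reports.

## Problem sizes used in the shipped validation

The test suite validates parameter recovery on cohorts of 10 subjects,
N = 10 networks, T = 290 volumes with 3 planted states, across 20
generator seeds with 20 k-means restarts per fit (the default of 500
restarts buys extra stability on real cohorts; for these well-separated
synthetic states a smaller number already attains the optimum, as the
exhaustive-partition oracle test shows at small M). Statistical calibration
uses 200 null cohorts (N = 6, 10 subjects/group, 200 permutations) for the
family-wise error rate and 2000 replicates for the rank tests. Large-sample
convergence checks (law-of-large-numbers recovery of planted correlations)
use T = 50000 single draws.

## Known limitations

- The graphical-LASSO solver targets the small-N regime of network-level
  analyses (tens of nodes); it is not tuned for hundreds of nodes.
- Elbow-based k selection is a heuristic; for flat validity curves the
  chosen k is sensitive to noise, which is why the supported range is the
  small 2..6 regime and the sensitivity path (re-running at fixed k) is
  exposed.
- The Mann–Whitney exact path enumerates subsets and is limited to small
  samples; larger samples use the tie-corrected normal approximation with
  continuity correction.
- `run_pipeline()` holds all subjects' window stacks in memory; cohorts of
  a few hundred subjects at network-level N are fine, voxel-level inputs
  are out of scope.
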