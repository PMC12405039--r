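---
title: "Brain spaces from functional connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain spaces from functional connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
library(dplyr)
```

## The model

A *brain state* is one subject's functional connectome at one visit: a
symmetric matrix \(\mathcal{G}\) whose entry \((i, j)\) is the Pearson
correlation between the fMRI time series of regions of interest (ROIs)
\(i\) and \(j\), with unit diagonal. `brainstates` treats the set of all
such matrices as a phase-space-like *brain space*: each state is a point,
and a change over time — healthy ageing, learning, or the onset and
progression of a neurological disorder — is a path between points.

Three constructions make this computable:

1. **Embedding.** The dissimilarity between two states is the Frobenius
   distance over the off-diagonal entries,
   \(d(A, B) = \sqrt{2 \sum_{i<j} (a_{ij} - b_{ij})^2}\) (the diagonal is
   identically 1 and excluded; a full-matrix implementation differs only
   by that constant). Multidimensional scaling (MDS) of the pairwise
   distance matrix places the states in a low-dimensional space — three
   dimensions by default, a choice of visualisation, not of principle —
   such that nearby points are similar connectomes.

2. **Attribution.** Each MDS axis is explained by the ROI pairs whose
   connectivity values correlate with the axis coordinate across states.
   A single ROI's impact on an axis is half the sum of the correlations
   of its incident pairs; the \(\tfrac12\) factor stops each pair from
   being counted once per endpoint, which gives the exact conservation
   identity \(\sum_i \mathrm{impact}_{i,d} = \sum_p \mathrm{corr}_{p,d}\)
   used as a correctness oracle in the tests. Pairs are also ranked by
   their plain cross-state sample variance (denominator \(M - 1\)).

3. **Operators and subspaces.** The transition from a state at one visit
   to the next is the *K-operator*. Its two-visit numerical form here is
   the additive difference \(K = \mathcal{G}(t{+}1) - \mathcal{G}(t)\),
   so applying \(K\) to the source state reproduces the target exactly
   and the ideal healing is the inverse \(K^{-1} = -K\). In the reduced
   space, the same transition is summarised per dimension by the
   percentage variation \(100\,|x_t - x_s| / |x_s|\), and attributed to
   pairs via \(\text{contribution} = \text{connectivity change} \times
   \text{axis correlation}\). Diagnosis groups form *subspaces*: the
   convex hull of their embedded states, with membership, pairwise
   separation and a trajectory-stability verdict (a brain is
   healthy-stable when all its states over time stay inside the healthy
   subspace).

## A worked run on synthetic data

```{r pipeline, eval = FALSE}
cfg <- cohort_config(seed = 1)
sim <- simulate_cohort(cfg)
cohort <- harmonize_states(sim$states)
embedding <- embed_states(state_distances(cohort), dims = 3)
attribution <- attribute_axes(cohort, embedding, k = 5)
glance(embedding)
```

Every artefact also flows through `run_pipeline()`, which consumes a
cohort manifest (CSV or YAML) and writes plain-text outputs: embedding
CSV with a JSON sidecar, attribution tables, K matrices, reduced-path
JSON, subspace JSON and a run log with the retained-ROI count.

## Parameters that matter

* **`transform` (connectivity)** — `"pearson"` (default) keeps entries in
  \([-1, 1]\); `"fisher_z"` applies \(\mathrm{atanh}\) off-diagonal.
  Pearson is the default because connectivity *changes* between visits
  are then bounded by 2 in magnitude, matching the scale on which the
  operator and contribution tables are read; the transform is exposed
  because variance-stabilised pipelines are common upstream.
* **`dims` (default 3)** — dimensions of the embedding; must be at most
  M − 1 for M states. Three is enough to visualise and is the scale on
  which percentage variations are reported.
* **`method` (MDS)** — `"classical"` (Torgerson double-centering +
  truncated spectral factorization, via `stats::cmdscale`) is the
  default because it is fully deterministic, which matters for
  reproducible coordinates and bit-identical pipeline re-runs. A seeded
  SMACOF stress-majorization alternative (`method = "smacof"`,
  `n_starts` restarts) is provided for badly non-Euclidean inputs, where
  it can reach lower stress than the spectral truncation. When more than
  30 % of the spectral mass is negative the embedding records a
  non-Euclidean warning.
* **`mode` (K-operator)** — `"additive"` by default: two-visit
  differences are signed, zero-centred and defined everywhere, and the
  per-pair "connectivity change" read-outs are differences. The
  multiplicative element-ratio form is kept as an option for operator
  notation compatibility; it is undefined where the source entry is 0
  (cells masked and counted) and invertible only when fully defined.
* **`tol` (geometry, default 1e-9)** — a point within `tol` of a hull
  counts as inside; two hulls are disjoint when their minimum distance
  exceeds `tol`.
* **`k` (top tables, default 5)** — rows in the per-axis ROI tables.

## Numerical choices

* **Symmetry and range validation**: matrices must be symmetric within
  1e-12; entries within 1e-9 beyond \(\pm 1\) are clamped, anything
  further is an error. Label matching is exact string match after
  trimming whitespace — no fuzzy atlas mapping.
* **Missing ROIs** are whole-NA (or whole-zero) rows-and-columns.
  Harmonization keeps exactly the ROIs present in every state, in the
  first state's order, and is idempotent; fewer than two shared ROIs is
  a hard error.
* **Eigenvalue ties** in classical MDS follow `eigen`'s descending order
  with stable original-index tie-break; an all-zero distance matrix
  embeds to the origin with stress 0. Stress is Kruskal's stress-1.
* **Convex hulls without qhull**: membership, point-to-hull distance and
  hull–hull distance are computed by a Wolfe min-norm-point active-set
  solver over the member points (hull–hull via the Minkowski-difference
  point set), exact to machine precision at cohort sizes; hull vertices
  are identified by leave-one-out membership. Degenerate hulls (fewer
  than D + 1 affinely independent members) are flagged and handled in
  their affine span rather than rejected, since small cohorts are the
  normal regime.
* **Trajectory verdict rule** (a declared convention, since "stable"
  admits no unique formalisation): all states inside → healthy-stable;
  two or more inside/outside switches → oscillating (the epilepsy /
  mood-disorder pattern); anything else → diseased, including a single
  excursion that has returned but whose stability is not yet
  demonstrated.
* **Percentage variation** uses the source coordinate as baseline;
  dimensions whose source coordinate is below 1e-12 in magnitude report
  an undefined percentage (`NA`) plus the absolute change. Report
  rounding conventions: 2 decimals for percentages, 3 for contributions.
* **Impact normalisation**: raw half-sums are reported by default;
  `normalize = TRUE` divides by the incident-pair count \(N - 1\),
  yielding values on a correlation-like scale comparable across cohort
  sizes. Zero-variance pairs or axes get correlation 0, not `NaN`.

## The synthetic cohort generator

Real multi-site cohorts of this kind are access-restricted, so the
package ships a generator whose ground truth is known exactly. The
healthy template is a block-structured correlation matrix (default 20
ROIs in 4 communities of 5; within-block correlation 0.6, between-block
0.05). Disorder groups are block-structured perturbations of the
template — the defaults weaken one community's internal coupling by 0.4
per group, a strong but realistic effect for contrasting disorders — and
one group carries a follow-up visit whose truth differs from baseline at
a single pair (−0.35), so the true additive K is known. Any edit that
breaks positive semi-definiteness is projected to the nearest valid
correlation matrix (Higham alternating projections via
`Matrix::nearPD`, tolerance 1e-8, 1000-iteration cap); PSD-preserving
edits are returned exactly.

States are sampled by drawing `series_length` (default 500) multivariate
normal time points from the group truth — optionally plus white sensor
noise (`noise_scale`, default 0, since finite series length is itself
the modelled noise source) — and running the same connectivity
computation as real data, so every synthetic matrix is a realizable
correlation matrix with realistic sampling error of order
\((1-\rho^2)/\sqrt{T}\). Missing ROIs are injected per state at
`missing_roi_rate` to exercise harmonization. Per-state seeds derive
deterministically from the config seed: identical configs reproduce
bit-identical cohorts.

What the generator does *not* emulate: BOLD autocorrelation and spectra,
scanner/site batch effects, head-motion artefacts, atlas misalignment,
and age/sex effects on connectivity. Passing the recovery tests
therefore shows the machinery is correct and sensitive at realistic
noise levels, not that the method's anatomical read-outs on restricted
clinical cohorts are reproduced.

## Problem sizes used in the shipped checks

The validation suite runs cohorts of 20 ROIs (190 pairs) with 8 subjects
per group and series length 500 across 20 seeds for ground-truth
recovery — group silhouette, pairwise hull disjointness and the rank of
the edited pair among axis contributions — plus a 170-ROI,
3-state fixture with 10 ROIs missing somewhere to pin the harmonization
count at 160. These sizes give stable statistics while keeping a full
run in seconds; the generator scales to larger cohorts by configuration.

## Known limitations

* Axis signs and orientations are arbitrary (MDS indeterminacy): pair
  and ROI attributions are comparable only within one fitted embedding;
  all internal comparisons use distances or rank structure.
* Convex hulls are a geometric idealisation of a diagnosis region; with
  very few members they under-cover, and probabilistic basins of
  attraction are out of scope.
* The attribution tables are exploratory rankings; no permutation or
  parametric inference is attached to them.
* The two-visit K is a finite difference; parametric, time-continuous
  operator forms are out of scope.
* Raw fMRI preprocessing (registration, nuisance regression, bandpass
  filtering, atlas extraction) happens upstream; the package starts from
  ROI time series or matrices.
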