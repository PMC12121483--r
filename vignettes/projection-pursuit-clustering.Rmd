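---
title: "Methods: projection pursuit clustering and label transfer in appclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projection pursuit clustering and label transfer in appclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appclust)
```

## Why project before clustering

Clustering directly in a high-dimensional feature space runs into the empty
space phenomenon: local neighbourhoods are empty, so density-based methods
lose power exactly where biological data need it most — rare populations
sitting amid abundant ones. `hypercube_fraction(10, 0.63, 1e6, seed = 1)`
makes the point concrete: only about 1% of uniform 10-D data falls in a cube
that would hold 63% of it in one dimension. Manual cytometry gating has
always answered this by working in sequential 2D projections, where density
estimation is easy; `appclust` automates that strategy.

## The clustering model

The estimator assumes that cluster structure, where it exists, is visible as
a low-density valley in at least one orthogonal 2D projection of the data.
Each recursion step:

1. maps every projection pair of the current subset onto the unit square
   using the subset-local per-axis min and max (recomputed every step, so
   child subsets regain full resolution);
2. builds a 2D histogram with per-axis bin count
   `N = 4σ[3(n−1)²/4]^0.1` and smooths it with an isotropic Gaussian of
   width σ bins;
3. searches for decision boundaries as dynamic-programming extremal paths of
   the gravity-augmented density `H₁ = H + k·(y − y₀)²`, one start level
   `y₀ = q` per lattice point `q ∈ {0, 0.1, …, 1}`, keeping only levels
   where the path action `S(q)` (raw density integrated along the path) is a
   strict two-sided local minimum;
4. ranks surviving boundaries by the Calinski–Harabasz index of the two-way
   split they induce and cuts along the globally best one, then recurses on
   both sides.

Recursion stops when a subset is smaller than `2 × min_cluster_size` or no
candidate leaves `min_cluster_size` events on each side. Termination is
guaranteed by the size argument alone: each accepted split removes at least
`min_cluster_size` events from each side, so the leaf count never exceeds
`n / min_cluster_size`.

## Parameters

- `min_cluster_size` (events; required). The smallest population the analyst
  expects. It is both the stop rule and the candidate filter. Reducing it
  can only add structure: the cluster count is nondecreasing, though the new
  partition is not guaranteed to be a strict refinement of the old one —
  each level re-runs the full search and may cut elsewhere.
- `sigma` (bin units; default 1.0). Gaussian smoothing width. It enters the
  bin-count rule multiplicatively, so raising σ adds bins in proportion and
  the effective kernel width in data units stays roughly constant; the
  default of one bin unit keeps single Gaussian populations unimodal on the
  grid without washing out genuine valleys. It is a free parameter, exposed
  for tuning on other data types.
- `beta` (dimensionless; default 0.1, "10% gravity"). Scales the coupling
  `k = β(max H − min H)/max H_g` between the data density and the parabolic
  anchor. Zero removes the straightening entirely; large values force flat
  boundaries. The default works well across the regimes exercised here.
- `dq` (default 0.1). The gravity-level lattice step; 11 levels per
  orientation. Finer steps find valleys whose anchor falls between lattice
  points at proportionally higher cost.
- `bins` (optional). A fixed per-axis bin count that overrides the
  sample-size rule wholesale — useful for large cytometry samples where a
  constant grid (e.g. 50) is conventional and faster than the rule's growth.
- `step_limit` (default 1). The DP move bound per column. One-row moves give
  the closest discrete analogue of a continuous trajectory; the bound is
  exposed because steeper boundaries can need larger jumps at coarse grids.

## Numerical choices

- **Bin-count rounding.** The bin formula is non-integer; it is rounded half
  away from zero and clamped to at least 4 — a 2×2 or 3×3 grid cannot carry
  a meaningful path.
- **Binning convention.** Half-open bins `[e_i, e_{i+1})` with the final bin
  closed, so coordinate 1.0 belongs to the last bin; bin indices are 0-based
  at the interface and 1-based internally (R convention).
- **Mass-preserving smoothing.** Convolution uses a column-normalised
  Gaussian transfer matrix: each source bin redistributes exactly its own
  mass, with the kernel truncated and renormalised at the grid edges, so
  `sum(H)` equals the event count to machine precision. Smoothing happens
  before the gravity term is added.
- **Discrete extremals.** The variational problem is solved as a
  shortest-path DP over grid columns with the start row anchored at `y₀` and
  the end row free. Cost ties are broken toward the row nearest `y₀`, then
  toward the lower row index — deterministic, and consistent with the
  gravity prior. The DP is verified against exhaustive path enumeration in
  the test suite.
- **Action on raw density.** `S(q)` integrates the smoothed histogram *H*,
  never `H₁`: gravity guides the search but must not contaminate the valley
  score. Bin-centre sampling with uniform `Δx = 1/N` is used; no
  higher-order quadrature.
- **Endpoint levels.** `q = 0` and `q = 1` can never satisfy the strict
  two-sided minimum condition and are therefore never boundaries; this is
  accepted as specified rather than patched with one-sided rules.
- **Assignment tie rule.** Events exactly on a boundary ordinate go to the
  "below" side.
- **Global tie-break.** Candidate splits are ordered by CH score, then
  dimension pair (lexicographic), then orientation (boundary as a function
  of x before y), then lower `q0`. With ties resolved, the whole fit is a
  pure function of its inputs: projection searches are independent and may
  run in any order (or concurrently) without changing the result.
- **CH in the projection.** The Calinski–Harabasz score is computed in the
  2D unit-square coordinates where the boundary lives, not the full feature
  space: boundaries are ranked per projection, and scoring in the projection
  keeps scores comparable across pairs whose raw scales differ. A split
  with zero within-group dispersion scores `Inf` and outranks all finite
  scores. All admissible candidates across all projections are evaluated
  before choosing; there is no early exit.
- **Degenerate inputs.** Constant axes flag the projection as degenerate and
  it is skipped; non-finite values are an error naming the offending column;
  `d < 2` is an error.

## Label transfer

The benchmarking pipeline has four steps: (1) supervised UMAP on the
labelled training sample with `target_weight = 0.5`, weighing the feature
geometry and the prior labels equally — events with missing labels
contribute through the feature term only; (2) projection of the test sample
into the fitted embedding; (3) clustering of the test sample in the two
embedded dimensions, followed by maximum-overlap one-to-one alignment
(Hungarian assignment on the contingency table) of test cluster IDs to
ground-truth IDs — surplus or zero-overlap clusters stay unmatched; (4) a
misclassification report: an event counts as misclassified when its
translated label differs from truth, events of unmatched clusters count
wholesale, and per-cluster rates are listed by decreasing abundance with
per-cluster F1.

The 2D clusterer is pluggable behind a one-argument contract (n×2 matrix in,
integer IDs out, no noise label). The default is a density-mode seeker on
the package's own smoothed histogram: every occupied bin hill-climbs its
8-neighbourhood to a mode, and shallow modes are merged by topographic
persistence — a mode whose height above its best connecting saddle is less
than `merge_ratio` (default 0.2) of its peak is sampling noise on a larger
basin, not a population. This default favours robustness on well-separated
embeddings over sensitivity to barely-resolved substructure; support-vector
or model-based clusterers can be swapped in where that trade-off is wrong.
The alignment step is a maximum-overlap stand-in for quadratic-form matching
procedures used in cytometry; exact agreement with those is not claimed.

The embedding step doubles as a quality control on the ground truth:
`check_label_topology()` splits each label's embedded events in two (2-means
seeded deterministically at the extremes of the label's first principal
axis) and scores the split's silhouette. A genuinely homogeneous population
scores near 0.4 — the value a forced split of one Gaussian lobe produces —
while a label spanning two separated regions scores near 1; the default
flag threshold of 0.6 sits between the two regimes.

## What the synthetic generators emulate — and what they do not

`make_blobs()` samples labelled Gaussian mixtures with exact per-component
allocation (largest-fractional-part remainders), so fixture sizes are
deterministic. `four_blob_spec()` places four unit-variance components ≥10σ
apart in 3D — the clean multimodal regime. `make_rare_mixture()` builds the
imbalanced regime that motivates projection pursuit: a 2% component
separated from the abundant mass along exactly one axis and overlapping it
everywhere else. `eight_component_spec()` provides the labelled mixture for
transfer benchmarks (≥8σ between components in 5D).
`hypercube_fraction()` is the empty-space demonstration.

These generators produce spherical, noise-free, pre-transformed Gaussian
components. They do not emulate fluorescence spillover, arcsinh/logicle
transformation artefacts, scRNA-seq count noise, correlated markers, or
populations separated only in oblique directions. Passing tests therefore
demonstrate the machinery — valley detection, recursion, alignment,
reporting — under conditions where the answer is unambiguous; they do not
certify performance on real cytometry or expression data, where separations
are weaker and populations heavy-tailed. In particular, structure visible
only in rotated (non-orthogonal) projections is invisible to this search by
design; rotation search is deliberately out of scope.

## Problem sizes

The test-suite and acceptance-script regimes are sized for sharp expected
outcomes: 2,000 events for the four-blob recovery (`min_cluster_size` 50),
10,000 events with a 200-event rare component (`min_cluster_size` 100),
4,000 + 4,000 train/test events for the transfer pipeline, 10⁶ Monte-Carlo
draws for the hypercube fraction, and grids up to 6×6 for the exhaustive
path-enumeration oracle. At these sizes a full fit takes well under a minute
on one core; the dominant cost of the transfer pipeline is the UMAP fit.

## Known limitations

- Boundaries are axis-pair orthogonal projections only; rotated structure
  is not found.
- The strict two-sided minimum condition means valleys anchored exactly at
  the scan endpoints are not usable as boundaries.
- The q-lattice (`dq = 0.1`) can miss very narrow valleys whose action
  minimum falls between lattice points.
- The CH ranking favours balanced, compact splits; highly elongated
  clusters may be cut where a human would not.
- Labels are hard assignments; there is no merging step, so an early
  spurious split cannot be undone downstream.
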