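---
title: "Methods: trace evaluation and dynamics analysis for 3D+t particle data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace evaluation and dynamics analysis for 3D+t particle data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(track4d)
```

track4d is the computational core of a proofreading workflow for 3D+t
(4D) particle microscopy: volumes of moving compact objects ("blobs" —
cells, vesicles, insulin granules) imaged over time, annotated with
per-frame 3D markers, compared against expert gold standards, and
characterized by trajectory descriptors that feed a clustering analysis of
motion regimes. This vignette documents the models, the conventions, the
tunable parameters and the numerical choices, in that order of importance
to a user.

## Coordinate and data conventions

Everything in the package uses one convention, stated once and enforced
everywhere:

* axis order `(x, y, z)` maps to array dimensions 1–3 and frames to
  dimension 4; all coordinates are **0-based** and voxel intervals are
  **half-open** `[lo, hi)`. A voxel's center sits at its integer index.
* stacks are stored as one multi-page TIFF per dataset, pages ordered
  z-fastest (`page = t * nz + z`), with a JSON sidecar recording
  `nx, ny, nz, nt`, the dtype and its dynamic range. 8- and 16-bit
  unsigned stacks round-trip bit exactly; floating-point stacks are
  stored normalized over their declared range at 32-bit precision.
* a **trace** is a time-ordered sequence of markers `(t, x, y, z)`, at
  most one marker per frame; a trace set is a tibble with one row per
  marker, which is what every user-facing verb consumes and returns.

The upper-bound convention of the ROI intervals (exclusive) is a package
decision, chosen so interval lengths are simple differences and nested
crops compose by offset addition.

## The visualized volume and its transfer functions

Microscopy blobs are usually bright on dark; for display the package
works on the **negative** normalized image,
`view = (max_level - raw) / (max_level - min_level)`, so particles are
dark on white. Two opacity transfer functions act on this view:

* `opacity_threshold(view, base, theta)` zeroes the opacity wherever the
  visualized intensity **strictly** exceeds `theta`, which suppresses
  bright-view artifacts and residual impulse noise;
* `transparency_map(view, tau)` with `tau` in `[-1, Inf)`: for
  `tau <= 0` a constant opacity `1 + tau` (a global fade), for `tau > 0`
  the power law `view^tau`, making voxels that are bright in the original
  image the most transparent.

The exponent is applied to the *visualized* (negated, normalized)
intensity, not the raw grey level: applying it to raw values would make
bright voxels *more* opaque, the opposite of the intended behavior, and
normalization to `[0, 1]` is required for the power law to stay a valid
opacity. Two edge conventions: `0^tau` is defined as 0 for `tau > 0`
(continuity from above), and trilinear resampling clamps out-of-range
sample coordinates to the volume edge rather than inventing a background
value. Resampling places output sample `i` at input coordinate
`i / factor`, so factor 1 is exactly the identity and the output never
exceeds the input's extrema. The documented pipeline order is
transparency first, threshold second.

## Two-click marker placement

A click on the rendered volume defines a *piercing segment*: the chord of
the volume's bounding box along the viewing direction through the
un-projected click (orthographic projection). Two clicks from different
angles rarely produce intersecting chords, so the marker is placed at the
midpoint of the shortest segment connecting the two chords. The closest
points are computed on the bounded *segments* (parameters clamped to
`[0, 1]`), not on infinite lines — the chords end at the volume faces,
and so should the geometry.

Parallel segments (two clicks without rotating the view) do not error:
the midpoint of the overlap region is returned with a `degenerate` flag,
and the caller decides whether to reject. A configurable `warn_gap`
threshold flags picks whose residual gap is suspiciously large (a
mis-click); its default is off (`Inf`) because no principled value
exists — the gap scales with blob size and viewing geometry. The marker
is placed purely geometrically, with no snapping to local intensity
maxima.

## Evaluation against a gold standard

For one test trace `C` and its gold trace `G`, the package builds a
bipartite graph with an edge between every test/gold marker pair closer
than a distance gate `d` (and, by default, in the same frame), weighted

$$w_{cg} = \frac{1}{\epsilon + \lVert \vec c - \vec g \rVert},$$

and computes the maximum-weight bipartite matching. A matched test marker
is a true positive if its pair distance is below `d/2`; unmatched test
markers are false positives, unmatched gold markers false negatives.
Precision, recall and F1 follow as `TP/(TP+FP)`, `TP/(TP+FN)` and their
harmonic mean.

Decisions the definitions above do not determine:

* **matched-but-far pairs** (distance in `[d/2, d)`) count as one FP
  *and* one FN — the only convention that preserves the identities
  `TP + FP = |C|` and `TP + FN = |G|`, which the tests assert on every
  instance;
* **zero denominators** define the affected score as 0, so a fully
  missed trace scores 0 rather than NaN;
* **`epsilon`** defaults to 1e-9 voxels — it only guards coincident
  markers against division by zero and has no effect at realistic
  distances; `d` should be set to the expected object diameter
  (6 voxels for the default synthetic blobs);
* **matching is time-locked by default**: a prediction in the wrong
  frame is a tracking error, not a near-miss;
* **trace correspondence** between the two sets is an optimal one-to-one
  assignment maximizing the summed per-pair TP, with smaller summed
  matched distance as tie-break (implemented as composite matching
  weights); an explicit id mapping can override it.

Aggregation reports both views: the **macro** F1 (mean of per-trace F1,
the headline number) and the pooled **micro** scores, within each
duration-quality bin and overall. Traces are stratified by length `L`
relative to the set's mean length `F̄` into four bins — very low
(`L <= 0.25 F̄`), low, average, and good (`L > 0.75 F̄`). The boundary at
`0.75 F̄` belongs to *average*, so the bins partition the set.

## The 14 trajectory descriptors

From the ordered markers `p_f` at frames `F` the kinematic sets are: step
displacements `D`, turning angles `R` (arccos of normalized consecutive
step dot products, skipping zero-length steps), speeds `V = D / Δt` and
accelerations `A = ΔV / Δt`, where `Δt` is the frame gap (so frame gaps
shrink speeds rather than being ignored). The acceleration definition is
the forward difference of speeds over the gap — the dimensionally
consistent reading — and the speed set treats each step as the scalar
`D_f` (moments of a vector set would be undefined).

Six **route-based** descriptors: total displacement `Δ = ΣD`; mean and
sample standard deviation (`n - 1`) of the turning angles; tortuosity
`Δ / |p_last - p_first|` (path over chord, ≥ 1, undefined and flagged
`NA` for a closed path); and the energy `Σ_axes Σ_bins p²` and entropy
`-Σ_axes Σ_bins p log₂ p` of the per-axis coordinate distributions.
Eight **hourly-law** descriptors: mean, sample standard deviation,
skewness and raw (non-excess) kurtosis of the speed and acceleration
sets, with skewness and kurtosis built from population (`1/n`) central
moments.

The coordinate "pdf" is estimated as a normalized histogram with 10 bins
per axis over the trace's own min–max range. This estimator is a package
decision (no canonical choice exists): it makes energy and entropy
translation- and scale-invariant per trace, at the cost of comparing
distributional *shape* rather than absolute spread across traces; the bin
count is exposed as `n_bins`. A constant coordinate puts all mass in one
bin (energy contribution 1, entropy 0). Traces shorter than 4 markers
cannot fill every set; `extract_features()` errors, and the batch verb
`compute_features()` drops them with a logged count. Undefined
descriptors propagate as `NA` and are dropped (with a message) before
clustering.

## Clustering: EM mixture and the subset search

Features are standardized to zero mean and unit variance before
clustering — a mix of voxels, radians and bits has no meaningful raw
Euclidean geometry. The clusterer is a diagonal-covariance Gaussian
mixture fitted by expectation-maximization: k-means++-style seeding,
best of `n_init` restarts by log-likelihood, hard labels by maximum
responsibility. The log-likelihood trace of the winning restart is
checked to be non-decreasing on every fit; a restart whose component
empties out (responsibility mass below 1e-8) is re-seeded. Convergence is
declared when the total log-likelihood improves by less than `tol`
(default 1e-6) or after `max_iter` (default 500) iterations; component
variances are floored at 1e-6 to prevent singular collapse on duplicated
points.

`subset_search()` fits every non-empty subset of the `N` feature columns
(`2^N - 1` subsets, guarded at `N <= 20`) for each candidate cluster
count and scores each partition with four validity indices: mean
silhouette, Davies–Bouldin, Calinski–Harabasz, and a between/within
symmetry ratio defined here as the minimum between-centroid distance over
the maximum mean within-cluster distance to centroid. The last is this
package's documented approximation of a symmetry-based index whose
original formulation was not available; it is labeled as such and carries
the same "larger is better" orientation as the silhouette. Two summaries
are emitted, because either could be the one a reader wants: the sorted
silhouette profile per `k` across all subsets (does one `k` dominate
regardless of feature choice?), and a consensus winner by average rank
across the four indices with the Davies–Bouldin rank reversed (no
canonical combination rule exists; average rank is scale-free and treats
the indices symmetrically). Every fit draws its seed deterministically
from the search seed, so the whole search is reproducible.

## The synthetic scene generator

`generate_toy_dataset()` is the package's reference scene and fixture
factory: `n_blobs = 5` equally sized spherical blobs performing
independent random walks through a `50 × 50 × 50` voxel volume over
`100` frames, rasterized and corrupted with salt & pepper noise, returned
together with their ground-truth traces. The walk is i.i.d. isotropic
Gaussian with `step_sigma = 1` voxel per frame (a "random walk" needs a
step law; the isotropic Gaussian is the standard diffusive choice), and
the reflecting boundary keeps each center inside
`[radius, dim - radius]` so blobs never protrude. Rasterization paints a
voxel iff its center lies within `radius` (default 3 voxels, Euclidean)
of a blob center, at intensity 200 on background 20 (8-bit); noise
corrupts each voxel independently with probability `density = 0.01`,
split evenly between the dtype extremes. Radius, intensities and noise
density are package choices picked once so that blobs are clearly
separable at toy scale; blobs may overlap (no collision handling).

What the generator deliberately does **not** model: optical point-spread
blur, Poisson photon statistics, anisotropic voxel sizes, intensity decay
(bleaching), or particle appearance/disappearance and occlusion. Tests
that pass on this scene therefore certify the geometry, bookkeeping and
statistics of the pipeline — not robustness to realistic microscopy
degradation, which is exactly the part of a real workflow that manual
proofreading addresses.

## Validation problem sizes

The test suite validates the evaluation machinery on the full toy scene
(5 traces × 100 frames, `d = 6`), perturbing the ground truth with
Gaussian jitter: at jitter σ = `d/10` the macro F1 stays above 0.95, and
F1 degrades monotonically as σ grows to `d`. The clustering study uses
two simulated motion families — 25 isotropic random walks (step σ = 1)
vs 25 directed walks (unit drift + σ = 0.2 noise), 50 frames each — runs
the full `2^14 - 1` subset search for `k ∈ {2, 3, 4}` with 3 EM restarts
per fit (the restart count chosen for this study size; the package
default is 10), and checks that the consensus lands on `k = 2` across
seeds with EM labels matching the generating family. Matching and
geometry are checked against exhaustive-enumeration and grid-search
oracles on hundreds of random small instances.

## Known limitations

* The DiaTrack-style MAT and ilastik-style CSV dialects are documented
  assumptions about column layout and 1- vs 0-based conventions, not
  reverse-engineered format specifications; the importers reject
  anything that deviates.
* The MAT codec reads and writes only uncompressed little-endian double
  matrices — sufficient for trace exchange, not a general MAT reader.
* The evaluator assumes one-to-one trace correspondence; split/merge
  events and identity switches are out of scope, as are MOTA/HOTA-style
  linkage error taxonomies.
* Energy and entropy depend on the histogram estimator and bin count;
  comparisons across packages using kernel or integral estimators will
  differ by a deterministic transformation of the same data.
* The subset search is exhaustive by design; beyond ~20 features its
  cost doubles per added feature, and a screening step should replace
  brute force.
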