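---
title: "Methods: radial gradient analysis of nucleolar pre-ribosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radial gradient analysis of nucleolar pre-ribosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, algorithms, parameter choices and
numerical conventions behind `nucleogradient`, in the order the pipeline
runs them. It is the package's design record: wherever a procedure admits
more than one reasonable reading, the choice made here is stated together
with its rationale.

## Coordinate and data conventions

All volumes are MRC2014 grids addressed `(x, y, z)` with `x` fastest
(MRC storage order). Particle coordinates are 0-based voxel coordinates
with voxel centers at integers; the MRC header origin is carried as
metadata but ignored for geometry, because every analysis step works in a
single tomogram's own voxel frame. Writing is always mode 2 (float32);
modes 0/1/2/6 are read and promoted to double.

Volume standardization uses the population convention (divisor *N*):
the target is a normalization (mean 0, SD 1), not an inference about a
sample, and idempotence to 1e-6 is part of the contract. Standardization
is computed over the full volume; a sub-region option is deliberately not
guessed at — the analysis volume handed to the mass stage should already
be cropped to the region of interest if that is wanted.

Gaussian filtering (default sigma 3 voxels at the 13.68 Å working scale)
is separable with *reflective* boundaries, so interior features conserve
their integrated density and features near lamella edges are not dimmed
the way zero-padding would.

## Robust sphere fitting

The nucleolar surface is modeled strictly as a sphere. The single fit
step is the algebraic least-squares solution of
`x² + y² + z² = 2 c·x + (r² − |c|²)`; on noise-free spherical data it
matches the geometric distance-minimizing fit to machine precision
(tested against a direct `optim` oracle).

The robust iteration is: fit on the current inlier set; compute every
point's distance to the fitted center; the next inlier set is all points
within mean ± 1 SD of the *current inliers'* distance distribution. The
band is two-sided and re-entrant — previously rejected points return if
the new band covers them — and the fixed point is detected on the inlier
index set, exactly, not on parameters.

On continuous noisy data this band has no nontrivial fixed point: each
pass of mean ± 1 SD trims ~32 % of a Gaussian shell, so the set shrinks
geometrically. Iteration therefore stops at an exact fixed point, at a
repeated set (cycle), when the next set would drop below 4 points
(recorded as `collapsed`), or at `max_iter` (default 50; convergence in
practice takes < 15). The returned fit is the one retaining the most
points **among settled iterations**: a fit is settled once its RMS
residual is within 3× of the following iteration's, i.e. one more
rejection pass no longer changes the residual scale materially. The
initial all-points fit is never a candidate (it trivially maximizes the
count), and the first post-rejection fit is typically unsettled — its
band was computed under full contamination and measured center errors at
the 438-voxel scale are 4–8 voxels, versus < 1 voxel one iteration
later. The settled-count rule is the operational form of "iterate until
nothing changes, then keep the fit supported by the most points".

Per-tomogram fitting pools both precursor classes, reports failures
per tomogram without aborting the batch, and applies a minimum
retained-inlier count (default 10) in place of a subjective
"enough of the ring is visible" criterion.

## Mass analysis

Masses come from voxel counts:
`mass = voxels × (voxel_size·10⁻⁸ cm)³ × 1.3 g/cm³ / 1.66054·10⁻²⁴ g/Da`,
which makes one 13.68 Å voxel ≈ 2004 Da and a 4.5 MDa particle
≈ 2245 voxels.

The binarization threshold is calibrated per volume: starting at 5 (in
standardized units, safely above any foreground) and descending in fixed
steps of 0.05, the first threshold at which the mean mass of the
connected components nearest the reference particles reaches the target
(default 4.5 MDa) is kept. Reference masses are measured on the nearest
26-connected component within a search radius, not on a fixed box
integral, because components are what the working threshold defines.
The linear descent with first-crossing return is the minimal reading of
"decrease until the mean reaches the target"; the step is configurable.

Segmentation uses 26-connectivity (compiled flood fill), the default of
the segmentation tools in this field, which avoids artificially splitting
blobby particles. Components below 2 voxels are discarded and separately
accounted, object distances use centroids, and the 1D profile (mean mass
per 0.05-wide normalized-distance bin) reports empty bins as count 0 with
an undefined mean rather than zero. The 2D mass–distance spectrum stores
total mass per cell (0.25 MDa × 0.05 bins by default — ≥ 10 mass bins
across the 3–5.5 MDa spike); its grand total equals the summed object
masses exactly up to IEEE summation order. Touching particles merge; no
watershed splitting is attempted.

## Bias-mitigated template matching

The featureless reference averages picked subvolumes under independent
uniformly random rotations (unit-quaternion sampling, trilinear
resampling), leaving particle size and contrast but no internal features.
Matching is masked, locally normalized cross-correlation computed by FFT
at every valid translation: under the template mask, both template and
local patch are mean-subtracted and variance-normalized, so scores lie in
[−1, 1] and are invariant to affine intensity changes of the volume.
Translational search only: the featureless sphere is rotation-invariant,
and exhaustive angular search belongs to the dedicated external tools.
Peaks are 26-neighborhood local maxima, taken greedily by descending
score under non-maximum suppression (default radius: half the template
edge, preventing double picks of one particle).

Truncated references erase a spherical region to the template's
background mean and drop it from the scoring mask; everything outside the
erasure is bit-identical. The dual-reference consensus retains a particle
when the two hit lists contain points within 4 voxels (Euclidean, at the
matching scale — the per-axis alternative is configurable), pairing
greedily by ascending distance, each hit used once; the survivor sits at
the pair midpoint with the mean score. The retained set is symmetric in
the two lists. On featureless noise, two references with near-disjoint
masks retain hits only at the chance rate of minimum-separated random
lists — the property that makes the consensus a bias control.

## Replicated classification and consensus

Subvolumes are assumed pre-aligned (the upstream averaging step supplies
shifts and angles); classification scores every subvolume against every
class average by masked normalized cross-correlation. Initialization
assigns each subvolume to 2 random classes (the "oversampling factor 2"
is read as membership in two initial averages, flagged as an
interpretation) out of 10. For the first 10 iterations a simulated
annealing rule applies: the best-scoring class is taken unless a randomly
proposed alternative is accepted with probability
`exp((s_alt − s_best) · 100 / T)`, the temperature stepping linearly
10 → 0. The ×100 score scale makes the nominal temperature ramp span
correlation differences of order 0.1; the underlying tool's temperature
units are internal and unrecoverable, so the scale is explicit and
configurable, and the acceptance rule is a documented Metropolis-style
stand-in for its stochastic hill climbing. Afterwards assignment is
strictly best-score until < 1 % of subvolumes change class or 30 further
iterations pass. Empty classes keep their last average until repopulated.
Randomness is keyed to (seed, iteration, subvolume id) through a
deterministic integer hash, so permuting the input subvolumes together
with their ids permutes the assignments identically.

Consensus over six independently seeded replicates requires the same
reconciled label 5 of 6 times. Reconciliation has two routes: one-to-one
Hungarian matching of class averages against replicate 1 (when the class
count matches the true heterogeneity), or — when classification
deliberately oversplits, e.g. 10 classes for 3 structural states —
average-linkage hierarchical clustering of all replicates' class averages
(distance 1 − correlation) into the major classes, with the vote on major
labels. The clustering route is the one used in the validation suite,
since with oversplitting a subvolume legitimately wanders among sibling
classes of one structural state. A helper builds a focus mask from the
top decile of across-average voxel variance for a second, focused pass.

Map-to-map comparison resamples both maps to the coarser voxel size,
low-pass filters to the stated resolution (Gaussian with half-amplitude
at 1/resolution), and aligns globally by a coarse-to-fine ZYZ Euler grid
(30° grid, then 10° local refinement — the same final increment as a flat
10° search at ~20× less compute) with FFT translational alignment at each
pose. Alignment maximizes |NCC| and reports the signed value: EM contrast
sign is convention-dependent, and sign-invariant alignment is the only
rule under which an inverted copy aligns at its true pose and reports −1.
The fast rotational matching algorithm used at scale elsewhere is out of
scope; the grid search substitutes for it.

## Spatial statistics

Normalized distances divide by each tomogram's own fitted radius.
Radial PDFs are Gaussian-kernel density estimates on a grid covering the
data ± 4 bandwidths; the automatic bandwidth is Silverman's rule
`0.9 · min(SD, IQR/1.34) · n^(−1/5)`.

The Fisher–Pitman permutation test relabels pooled observations into
groups of the original sizes. Exhaustive mode (≤ 10⁶ distinct
relabelings) returns the exact fraction at least as extreme as observed;
Monte-Carlo mode (default 10⁵ draws) returns `(b + 1)/(m + 1)`, the
unbiased conservative estimate. Two-sided extremity compares |statistic|
(|log ratio| for the variance ratio), with a 1e-12 relative tolerance on
the comparison to keep ties stable in floating point. The variance
contrast defaults to the *difference* of sample variances, two-sided; the
ratio is available — which of the two the original analyses used is not
recoverable, and the default is documented rather than silently chosen.

Boxplot summaries use type-7 (linear interpolation) quartiles and
min/max whiskers by default, the convention of the figures this package
mirrors; the Tukey 1.5·IQR convention with explicit outliers is
available. Significance labels follow P ≥ 0.05 NS, ≤ 0.05 \*, ≤ 0.01
\*\*, ≤ 0.0001 \*\*\* (the boundary 0.05 maps to \*). Class abundances
are within-condition percentages. No multiple-testing correction is
applied anywhere, matching the analysis style being reproduced.

## The synthetic scenario generator

The generator is the package's study stand-in, with defaults encoding
the study conditions: a nucleolar sphere of 438 voxels (599 nm at
13.68 Å/voxel); three particle classes in radial shells at 0.85 / 0.95 /
1.00 of the radius (SD 0.05, 500 each, 3–5.5 MDa); a background
population uniform in the sphere volume with masses up to 2.5 MDa (the
radial law of the real background field is unknown, so uniform-in-volume
is the default and configurable); a 3–5.5 MDa surface spike; an optional
infinite plane-parallel slab emulating lamella cuts, enforced exactly by
rejection (`|n·p − offset| ≤ thickness/2`); and additive Gaussian noise
with foreground contrast 5 SD above it. Radial draws are
`radius × Normal(mean, sd)` resampled until positive — rejection, not
clipping, to preserve the unimodal shell shape. Rendered particles are
uniform-density discrete balls: the `round(mass/mass-per-voxel)` grid
voxels nearest the particle center, so rendered voxel counts match the
mass conversion to within discretization ties. Subvolume sets instantiate
fixed random blob templates (unit variance) with noise at a stated SNR
(signal variance / noise variance), so within-class correlation is
analytically `snr/(1+snr)`.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: missing-wedge anisotropy, CTF,
crowding and excluded volume between particles, realistic macromolecule
shapes (mass analysis only consumes voxel counts), non-spherical or
deformed nucleoli, and spatially varying background. Conclusions about
those effects need real tomograms.

## Validation scales

The test suite and the acceptance script run desk-scale versions of each
experiment, chosen as the smallest sizes at which the statistical checks
are stable: 26 tomograms × 500 particles for sphere recovery; 20
reference particles of 4.5 MDa in a 160×120×120 rendered volume for the
mass stage; 500–600 particles per shell for gradient and variance tests;
96³ search volumes with 11³ templates and 300-peak lists for matching;
300 subvolumes (16³) × 6 replicates for classification; 1000 simulated
null datasets at 199 permutations for the size of the test. Monte-Carlo
p-values in the acceptance script use 10⁵ draws, so their floor is
10⁻⁵; the much smaller p-values reachable on larger hardware require
only raising `n_perm`.

## Known limitations

Sphere fitting has no ellipsoid fallback, so strongly anisotropic
nucleoli bias the normalized distances. Threshold calibration assumes the
reference particles dominate their local components; in very dense
volumes the nearest-component rule can latch onto merged clumps.
Classification assumes pre-aligned subvolumes; only optional integer
shifts are provided, not a rotational refinement. The consensus filter is
greedy rather than optimal bipartite matching — at the ±4-voxel densities
involved the difference is below the random-matching noise. The CLI
covers the pipeline stages thinly; programmatic use through the exported
functions is the primary interface.
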