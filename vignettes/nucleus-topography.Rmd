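---
title: "Quantifying neuronal nucleus topography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal nucleus topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleotopo)
```

## The problem

Cranial motor nuclei are internally organised: subnuclei innervating
different extraocular muscles occupy stereotyped positions along the
dorsoventral (DV) and mediolateral (ML) axes, and adhesion perturbations
can scatter cells or shift whole subnuclei. Given per-cell 3D coordinates
(one row per detected nucleus centre, with larva, genotype, side and
marker status), `nucleotopo` answers three kinds of question:

1. *Dispersion*: are cells of one group spread over a larger volume, with
   fewer close neighbours? (convex-hull volume, Delaunay local density,
   Mann–Whitney comparisons at the per-larva level)
2. *Position*: where does a cell population sit on a normalised DV×ML
   grid, and how far and in which direction does it move between groups?
   (Dirichlet occupancy model, KL divergence, axis shifts, 2D KS test)
3. *Function and expression*: do behavioural gains and marker intensities
   change accordingly? (optokinetic analysis, background-corrected
   intensities)

Every analysis is driven end to end by a synthetic-data generator with
recorded ground truth, so recovery of known parameters — not agreement
with any particular dataset — is the package's standard of correctness.

## The occupancy model

Each larva's DV extent (anchored at its first and last reference cell
along z) is divided into `n_z = 15` equal bins, and its ML extent (from
the midline at `x = 0` to the lateral-most reference cell, using |x| so
both sides fold together) into `n_x = 4`. Binning is half-open with the
top edge closed, so the anchoring cells land in bins 0 and 14 (or 3) by
construction, and normalisation is per specimen *before* pooling —
larvae of different physical size contribute on a common grid. Pooled
counts $n = (n_1, \dots, n_K)$, $K = 60$, are the sufficient statistic.

Occupancy probabilities get a symmetric Dirichlet prior with per-bin
concentration $\alpha$; conjugacy gives the posterior in closed form,

$$ p \mid n \;\sim\; \mathrm{Dirichlet}(\alpha + n_1, \dots, \alpha + n_K), $$

which the default sampler draws from directly (normalised Gamma
variates). An MCMC mode (JAGS) is retained purely as a validation path:
because the model is exactly conjugate, the MCMC must reproduce the
closed form's per-bin means and variances within Monte-Carlo error, and
the test suite enforces this — it is the module's central oracle.

**Prior concentration.** The default is $\alpha = 1/K$, i.e. one
pseudo-cell spread over the whole grid (a Perks-type prior). The flat
$\alpha = 1$ alternative puts $K = 60$ pseudo-cells on the grid, which
at realistic sample sizes ($N \approx 280$–$400$) shrinks every
posterior mean position toward the grid centre by the factor
$N/(N + K\alpha) \approx 0.82$–$0.87$ and therefore biases a true 1-bin
axis shift to ≈0.87 bins. With $\alpha = 1/K$ the shrinkage is ≈0.3%
and recovery is essentially unbiased (the acceptance suite verifies a
mean recovered shift within ±0.1 bin and 90–99% credible-interval
coverage over 100 replicates). $\alpha$ is exposed in every function for
sensitivity analysis.

**Divergence and shifts.** For each paired posterior draw $s$ the
divergence $KL(p_a^s \| p_b^s) = \sum_k p_a^s[k]\log(p_a^s[k]/p_b^s[k])$
and the occupancy-weighted mean bin positions are computed; summaries
are the mean and central 95% interval (2.5–97.5 percentiles) over draws.
KL is asymmetric and the direction is a convention, so the reverse and
symmetrised (Jeffreys) means are always reported alongside. Shifts are
`a − b` in bin units: positive DV shift = group a more dorsal, positive
ML shift = more lateral. The terminal posterior sample size (default
20,000) is justified by a stability ladder (`convergence_check()`):
the KL mean must change by less than 1% (relative, with a small absolute
floor for near-zero divergences) when the sample count is increased.

**Numerical care.** With $\alpha = 1/K$, Gamma draws for zero-count bins
occasionally underflow to exactly zero; the KL kernel treats $p = 0$
terms as 0 (their true contribution) and floors $q$ at the smallest
normal double, keeping every divergence finite without distorting
overlapping-support comparisons.

**2D KS test.** The overall distributional difference is tested with a
quadrant-based two-sample Kolmogorov–Smirnov statistic: at each data
point of a conditioning sample the four open axis-aligned quadrants are
compared between the samples ($k$ = max absolute difference, conditioned
on each sample in turn and averaged). Quadrants use strict inequalities,
so points on an anchor line count for neither side — this keeps $k = 0$
exactly for identical samples and $k = 1$ for fully separated ones. On
an integer bin grid ties are pervasive and any asymptotic null is
invalid, so the p-value comes from label permutations, which are exact
under exchangeability but slightly conservative when the permutation
distribution of $k$ is heavily tied; simulated type-I error at nominal
0.05 sits at roughly 0.03–0.05 for 40-cell samples.

## Clustering metrics

The convex-hull volume is the volume of the smallest convex set
containing a side's coordinates. Local density at a cell is defined as
the reciprocal of the mean length of its Delaunay edges (1/μm, reported
as arbitrary units): densely packed cells have short edges to their
natural neighbours. This formula is one of several defensible
Delaunay-derived densities; it was chosen for being scale-covariant
(dilation by $s$ divides all densities by $s$, asserted to 1e-9 in the
tests), robust to neighbour count, and parameter-free.

Both measures are computed from one tessellation primitive: the 3D
Delaunay tessellation obtained as the lower convex hull of the points
lifted onto the paraboloid in 4D, built in compiled code by a
randomized-order incremental algorithm. Exact degeneracies (cospherical
or coplanar subsets — lattice-like fixtures trigger them) are broken by
a deterministic jitter of 1e-6 μm keyed to a seed; the jitter decides
combinatorics only, and all volumes and edge lengths are evaluated on
the original coordinates, so a unit cube's hull volume is exactly 1.
Correctness is enforced by a brute-force empty-circumsphere oracle and
closed-form volume checks in the suite.

Per-larva aggregation computes each metric per side and averages the two
sides; a side with fewer than 4 (hull) or 5 (density) cells is excluded
from the average with a warning rather than failing the larva. "Dorsal
half" selection, where requested, keeps cells at or above the midpoint
of the larva's own z range. Group comparisons use the two-tailed
Mann–Whitney U test, exact for combined $n \le 20$ without ties (the
regime of typical 6-per-group designs) and tie-corrected normal
approximation otherwise, without continuity correction.

## Optokinetic analysis

The stimulus is a constant-speed grating reversing direction every 6 s;
eyes are sampled at 100 Hz. Angles are stored rightward-positive for
both eyes, so nasal (toward the nose) means positive velocity for the
left eye and negative for the right.

- *Orientation from moments*: frames are binarised, connected components
  labelled (`EBImage::bwlabel`), the two largest kept, and orientation
  computed as $\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},
  \mu_{20}-\mu_{02})$, accurate to well under 1° for ellipse-like
  components; near-isotropic components (circles) are flagged
  orientation-undefined rather than reported.
- *Slow phases*: eye velocity is estimated by central differences after
  a 5-sample moving average; samples exceeding 3× the maximum stimulus
  speed are fast phases, excluded together with a 50 ms guard window
  (which also absorbs smoothing contamination); runs are additionally
  broken and guarded at stimulus reversals and must last ≥ 0.5 s.
- *Gain*: within each slow phase the eye velocity is the least-squares
  slope of angle against time, classified nasal/temporal by its sign
  for that eye; gain is the mean of |slope|/|grating speed| over
  qualifying phases. The slope estimator (rather than the mean of
  absolute sample velocities) matters: at 0.5° sample noise the folded
  absolute value of per-sample velocities would bias gains upward by far
  more than the ±0.02 bias the suite enforces, while the phase-level
  slope is unbiased. A phase with exactly zero slope has no direction
  and contributes its zero gain to both.
- *Range and dominance*: per-eye range is max − min angle over the
  session; the strong eye has the larger range, ties going to the left
  eye with a logged note. Resting-referenced excursions are reported as
  a secondary output.

## Intensity quantification

Measurements take five equally spaced slices from the interior of the
substack (excluding the first and last slice; depth ≥ 7 required), mean
grey values per ROI per slice per side, and subtract the average of
three background ROI means before averaging within specimen; negative
corrected values are reported, not clipped. The printed category bands
overlap at their endpoints, so the package adopts left-closed/right-open
bands: a value of exactly 1500 a.u. is `regular` and 3500 a.u. is
`large_bold`. Midline-convergence area is the count of supra-threshold
pixels in the sagittal plane at the midline times the squared pixel
size, with a connected-component report. Background ROIs are inputs:
the original selections were manual, and no automatic detection is
attempted.

## The synthetic generator: what it emulates, and what it does not

Generators are pure functions of a master seed, which is expanded into
independent sub-seeds per consumer (`split_seed()`), so a single integer
reproduces an entire run bit for bit.

- *Occupancy datasets*: per-larva cell counts drawn uniformly from a
  configurable range (defaults of 10–20 and 13–23 cells per larva over
  19 and 22 larvae reproduce the ~280 vs ~400-cell pooled sizes of
  realistic designs; per-larva count distributions are not calibrated to
  any dataset, only the totals), multinomial bins from a known grid,
  uniform placement within bin interiors, and three marker-positive
  reference cells anchoring each larva's extents so re-binning recovers
  the sampled bins exactly. The default grid is smooth, medially biased
  and mildly dorsally biased, with empty extreme DV rows so that
  `shift_grid()` can move it a whole bin without losing mass — making
  the true shift of shifted variants exactly the nominal value.
  Physical extents are fixed at 30 μm (DV) and 12 μm (ML), a typical
  larval subnucleus scale.
- *Clustered nuclei*: Gaussian mixtures whose per-axis spread is
  multiplied by a scatter factor (1 = compact wild-type-like, 3 =
  scattered), the contrast driving the hull/density comparisons.
- *Eye traces*: triangular-wave stimulus, per-direction gains, Poisson
  resetting saccades (instantaneous return to rest — only slow phases
  are analysed, so saccade dynamics are irrelevant), additive Gaussian
  angle noise; true slow-phase intervals are recorded for segmentation
  tests.
- *Frames and stacks*: rasterised ellipses with optional salt specks
  kept clear of the eyes; Gaussian intensity stacks around stated ROI
  and background means.

None of this emulates microscopy point-spread functions, detection or
curation error in the coordinates, nerve trajectories, per-larva random
effects (cells are pooled, as in the model), eye-tracking segmentation
failures, or developmental dynamics. Passing tests therefore demonstrate
that the estimators recover the truth of this generative family at
realistic sizes and noise levels — not that any particular biological
dataset satisfies those assumptions.

## Problem sizes and runtimes

The test suite and the acceptance script use: 20 random grids for the
MCMC-vs-closed-form oracle (1,500 draws each, MC-SE from effective
sample size); 100 replicates at ~280 vs ~400 cells for shift recovery
(3,000 posterior draws per group); 500 null simulations × 999
permutations (40-cell samples) for KS calibration; 60 s traces at
100 Hz for gain recovery; 20,000 posterior draws wherever a single
analysis is summarised. These sizes keep the full suite under a minute
on one CPU while leaving Monte-Carlo error well inside every asserted
tolerance.

## Known limitations

- The Delaunay-density formula is a documented convention; other
  definitions (simplex volumes, cell areas) would order groups the same
  way but produce different absolute values.
- The occupancy model ignores inter-bin spatial correlation (no
  smoothing prior) and per-larva heterogeneity; it is a pooled
  multinomial by design.
- KL magnitudes depend on the prior concentration through the smoothing
  of empty bins; cross-study comparisons should fix $\alpha$.
- The incremental hull uses double-precision predicates with seeded
  jitter; pathological inputs far outside the μm coordinate scale
  (e.g. coordinates ~1e-6 apart) would need a smaller jitter.
- The permutation KS p-value is conservative under heavy ties; with
  40-cell samples on a 60-bin grid the effective type-I error at nominal
  0.05 is ~0.03–0.05.
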