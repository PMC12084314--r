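---
title: "Voxel-volume morphometry for crispant screens: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-volume morphometry for crispant screens: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmorph)
```

## The measurement model

Nonlinear registration of a subject brain to a reference atlas produces an
atlas-to-subject transform `phi(x) = x + u(x)`, sampled at atlas voxel
centres with `u` in micrometres.  All volumetric information about the
subject lives in the Jacobian of this map:

* `J(x) = I + grad u(x)`, with the displacement gradient estimated by
  central finite differences in the grid interior and one-sided stencils
  at the boundary, each scaled by the voxel spacing;
* `LJD(x) = ln det J(x)`, the log-Jacobian-determinant.  Under the
  atlas-to-subject convention used throughout, `LJD < 0` means the
  subject is locally *smaller* than the reference (the equivalent view is
  that the subject had to be inflated to match the atlas).  The finite
  difference scheme is exact for affine transforms, so a uniform linear
  scale `s` yields `LJD = 3 ln s` at every voxel, including boundaries;
* the subject-space volume of any atlas region `M` is the integral
  `V(M) = sum_{x in M} exp(LJD(x)) * voxel volume`, reported absolutely
  (um^3) and as a percentage of the total brain volume computed the same
  way.

Two deliberately different routes to the same quantity guard against
implementation error.  `warp_volume_oracle()` never differentiates
anything: it maps the corners of every (optionally subdivided) voxel cell
through `phi` by trilinear interpolation and sums tetrahedral volumes of
the mapped hexahedra.  This purely geometric construction is exact for
affine maps and converges quadratically for smooth fields; the test suite
requires the two routes to agree within 1% on random smooth fields, and
the synthetic generator uses the geometric route to record per-division
ground-truth volumes.

## Voxelwise statistics

Group comparison is performed independently at every voxel on subject
maps (LJD or fluorescence intensity):

* **Two groups** — a two-sided two-sample t-test.  The default is the
  pooled-variance Student test; Welch is available
  (`var_equal = FALSE`).  Zero-variance voxels are set to `p = 1` rather
  than `NaN` so that maps stay total, and are counted in the output.
* **Two experiments combined** — the additive linear model
  `y ~ genotype + batch` (no interaction), with the genotype main effect
  tested by the Type II F statistic: the residual-sum-of-squares drop
  from the batch-only model to the full model, over the full-model
  residual mean square.  For balanced designs this is the classical
  two-way ANOVA; for unbalanced cells it is the standard Type II test of
  a main effect while controlling for batch.  With a single batch level
  the model collapses to one-way ANOVA.

Both statistics are computed by vectorized projection algebra across all
voxels at once, and the tests require exact agreement (to 1e-8) with
per-voxel `t.test()` and `lm()`/`anova()` fits at randomly sampled
voxels.

## ROI definition: threshold, symmetry, cluster extent

`filter_significance()` converts a p map into a region-of-interest mask
in three steps, each recorded in the mask's provenance:

1. threshold `p < alpha` within the brain mask (`alpha = 0.01`);
2. optionally keep a voxel only if its mirror voxel across the atlas
   midsagittal plane also passes.  The mirror is the exact index
   reflection `i -> 2 * plane - i` (half-voxel planes supported); a
   Chebyshev tolerance radius `tol` (default 0) admits approximate
   homotopy;
3. remove connected components smaller than `min_cluster` voxels
   (default 50, 26-connectivity; both configurable).

The `alpha = 0.01` threshold follows the analysis this pipeline
re-implements; the cluster minimum, connectivity and exact-mirror rule
are this package's declared defaults, since no operational definition of
"small cluster" or "bilaterally symmetric" was available.  No voxelwise
multiple-testing correction is applied: the symmetry and cluster filters
are the false-positive control, which is why their calibration is tested
explicitly (below).

ROI-level inference then leaves the voxel domain: a discovered mask is
measured per subject (`% of total brain volume`) in an *independent*
cohort and compared by t-test (`roi_replication_test()`), or across three
groups by one-way ANOVA with unadjusted pairwise post hoc t-tests and an
optional Holm column (`three_group_roi_anova()`; error df `N - 3`, e.g.
39 for groups of 16, 14 and 12).  Post hoc p-values are reported
unadjusted by default because the re-implemented analysis reported plain
t-tests; the Holm column is provided for stricter readings.

## The synthetic cohort generator

`make_atlas()` builds a mirror-symmetric labeled phantom: an ellipsoidal
brain partitioned into forebrain, midbrain, hindbrain and a dorsal
cerebellar-plate slab, plus two spherical lateral-cerebellar-plate (LCeP)
subregions placed homotopically about the midsagittal plane.  The
geometry is parametric, so division volumes are known exactly.

`make_subject()` emulates the *output* of registration (registration
itself is out of scope):

* **Background deformation** — per-component Gaussian-filtered white
  noise, normalized to a per-component amplitude.  Defaults: correlation
  length 8 um, amplitude 0.8 um at 2 um voxel spacing.  These were chosen
  once as a plausible residual-registration variability — small relative
  to a 10% linear volume phenotype, and safely inside the regime where
  `det(grad phi) > 0` everywhere (the generator verifies positivity and
  regenerates at 70% amplitude if a field ever folds, recording the
  attempt count).
* **Programmed phenotype** — a radial contraction of linear scale
  `s` about each LCeP sphere centre: exactly linear out to the sphere
  radius plus a 2-voxel plateau margin, then a raised-cosine falloff to
  the identity over 0.6 sphere radii.  The plateau margin guarantees that
  every cell and interpolation stencil touching an LCeP voxel sees the
  pure linear map, so the ground-truth volume ratio of the labeled LCeP
  is *exactly* `s^3`.  The full-scale zone (plateau clipped to the brain)
  is what `effect_region_mask()` returns and what a discovered ROI is
  scored against.
* **Channels** — per-division baseline intensities for three fluorescence
  channels plus smooth noise; intensities are atlas-space, so volume
  phenotypes leave them unchanged.
* **Seeds** — every generator is a pure function of its seed; cohort
  subjects draw deterministic seeds from the design's master seed, and
  the manifest records them.

Default study designs (`default_config()`) mirror the emulated screen:
discovery 14 vs 14, replication 14 controls vs 17 crispants, rescue
16/14/12 with the doubly-injected group restored to `contraction = 1`,
`s = 0.9` for affected groups.

What the generator does *not* emulate: realistic neuroanatomy,
registration failure modes (misregistration, topology changes),
intensity-dependent registration bias, microscope PSF or shot noise, and
spatially varying deformation smoothness.  Passing tests therefore show
that the *statistics* behave as designed under a known geometric model,
not that any particular real cohort is free of registration artifacts.

## Calibration, power, and a known limitation of the symmetry filter

The test suite measures, at the study's own cohort sizes:

* **Type-I control** — on null cohorts (no contraction, n = 10 per
  group, 48^3 grids) the fraction of in-brain voxels with `p < 0.01` is
  ~0.009 (the LJD of a smooth random field is nearly Gaussian, leaving
  the t-test slightly conservative).
* **Recovery** — with `s = 0.9` and 14 subjects per group, the
  discovered ROI overlaps the programmed region with median Dice ~0.67,
  and the ROI deficit replicates (`p < 0.05`) in essentially all
  independent batches.
* **Rescue** — the three-group design reproduces the qualitative pattern
  (affected < control significant, double ~ control) in the large
  majority of seeds.

One calibration property fails by a measurable margin and is worth
understanding: with the exact-mirror symmetry rule plus the 50-voxel
cluster filter, null cohorts yield a *non*-empty ROI in roughly one run
in five, not less than one in ten.  The cause is geometric, not a coding
error: voxels near the midsagittal plane are their own near-mirrors, and
under a spatially smooth deformation field their t-values are strongly
correlated with their mirror values, so the joint pass probability there
is close to `alpha` rather than `alpha^2`.  Surviving null voxels sit at
a median distance of half a voxel from the plane, and midline-straddling
blobs occasionally exceed the cluster minimum.  Practical consequences:
the bilateral-symmetry filter provides genuine left-right replication
evidence only *away* from the midline, and discovered ROIs hugging the
midsagittal plane deserve extra scrutiny (or a replication cohort, which
is the design this pipeline automates anyway).

## The screen's companion statistics

* **Fragment analysis** — traces are baseline-corrected by a rolling
  minimum (window 40 bp, much wider than a peak), peaks called by local
  maxima with a prominence floor (2% of the maximum by default), windows
  delimited by inter-apex minima and trimmed to the contiguous region
  above 2% of apex height (a cut that keeps > 99.5% of a Gaussian peak
  and cancels in area ratios), and integrated trapezoidally.  The
  wildtype fraction is the area within ±2 bp of the expected product
  size over total area; a guide is *efficient* when this is strictly
  below 0.5, and a larva is included when any guide is efficient.  The
  strict inequality and the any-guide rule follow the re-implemented
  protocol; the peak-caller itself is a documented stand-in for the
  sequencer's proprietary software, validated on synthetic truth
  (recovery within ±0.05 across wildtype fractions 0.1-0.9).
* **Expression overlap** — genes with base mean below 100 in *either*
  experiment are removed (boundary kept); BH FDR is applied per
  experiment (via `p.adjust`); significance is strict at adjusted
  `p < 0.1`.  Convergence between the two experiments is tested by a
  one-sided Fisher exact test on the 2x2 membership table over the
  post-filter universe, with direction agreement counted but not entering
  the test.  This construction was one of several plausible ones; it is
  recorded in the output, and as a point of interest, with significant-set
  sizes 125 and 842, overlap 31 and a 17,629-gene universe it evaluates
  to p = 1.9e-14.
* **qPCR** — `delta Cp = Cp_reference - Cp_target`, relative expression
  `2^(delta Cp)` (one cycle earlier = two-fold more transcript), with
  both raw and control-normalized values emitted because the choice of
  normalization was left open; group pairs are compared by two-sided
  t-tests.

## Numerical choices and degenerate inputs

* Finite differences: central in the interior, one-sided at boundaries;
  exact for affine fields.  A field with `det <= 0` anywhere is rejected
  with the offending voxel count (the generator never produces one).
* Zero-variance voxels: `p = 1`, counted, never `NaN`.
* Empty ROI masks are a valid filter result; empty *input* masks to
  volumetry are an error.
* Boundary conventions are strict everywhere a rule says "less than":
  wildtype fraction 0.5 is not efficient, adjusted p exactly 0.1 is not
  significant, base mean exactly 100 survives the filter.
* Connected components are labeled through an adjacency graph
  (`igraph::components`), tested against an independent flood-fill.

## Problem sizes

The shipped tests run the calibration study at 48^3 (50 null cohorts,
20 recovery seeds, 20 rescue seeds) and the unit checks at 32^3 or
smaller; `scripts/acceptance.R` uses 12 null cohorts and 8 seeds per
stochastic quantity.  All sizes are package choices balancing statistical
resolution against a desk-scale run; every simulated experiment scales to
larger grids by configuration only.
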