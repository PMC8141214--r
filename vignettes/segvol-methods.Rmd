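---
title: "Methods: segmentation refinement operations in segvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation refinement operations in segvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segvol)
```

`segvol` implements the computational core of manual refinement of 3D
nuclear instance segmentations: pre-segmentation, voxel- and region-level
editing, splitting of fused nuclei, region bookkeeping, and the reliability
and timing statistics of the annotation workflow. This vignette documents
the models, the parameters that matter, the numerical conventions, and the
design decisions that were genuinely open.

## Data model and conventions

Volumes are dense arrays indexed `[z, y, x]`, 1-based as usual in R, with
physical voxel spacing `(dz, dy, dx)` in micrometres. The default spacing,
`(2.50, 0.75, 0.75)`, reflects light-sheet acquisitions in which in-plane
resolution is much finer than slice thickness; it is applied to formats that
carry no spacing (TIFF) and can be overridden. NIfTI spacing is honored from
the header. Multi-file TIFF stacks are ordered by plain lexicographic
(byte-order) filename sort — deterministic and easy to reason about, at the
cost of requiring zero-padded slice numbers.

Connectivity is defined on the voxel grid, ignoring anisotropy: 6 =
face neighbors, 26 = full 3D neighborhood. The default is 26 everywhere,
because nuclei are blob-like and face-only connectivity fragments diagonal
contacts; it is configurable on every entry point that labels components.
Anisotropy enters only where physical distance matters, and the only
distance-dependent operations (brush, grow, shrink) act in the X–Y plane,
which is isotropic, so distances are computed in voxel units.

Two conventions had to be fixed where common practice varies:

* **Foreground rule `intensity >= threshold`** (not `>`), shared by the
  pre-segmentation and the split sweep, keeping boundary voxels exactly at
  the threshold inside the foreground.
* **Component numbering**: components are labeled 1..K in order of first
  encounter in (z, y, x) raster order, so labelings are reproducible across
  runs and platforms.

## Pre-segmentation

`otsu_threshold()` maximizes the between-class variance over a 256-bin
histogram of the whole volume and returns the lower edge of the first
foreground bin; ties go to the lowest qualifying edge. A constant volume has
no threshold and is a degenerate-input error. `threshold_segment()`
binarizes and labels connected components; deliberately, no minimum-size
filtering is applied — noise specks are visible, sortable by size in the
region table, and removable by editing, which keeps the pre-segmentation a
pure function of threshold and connectivity.

## Editing operations

**Brush.** Paint and erase act on one Z-slice with a disc of configurable
radius (voxel center within Euclidean radius, in-plane). Painting is
authoritative: it reassigns whatever it covers, which is the only way to fix
an arbitrary labeling error. Erasing is restricted to the selected region so
a slip cannot damage neighbors.

**Constrained grow/shrink.** Selecting a voxel outside (grow) or inside
(shrink) a region sets two bounds at once: an intensity bound `t` (the
selected voxel's intensity) and a distance bound `d*`. For growth, `d*` is
the selection's in-plane distance to the nearest region voxel of that slice;
eligible voxels have intensity `>= t`, lie within `d*` of the region, are
background, and are 8-connected to the region through the eligible set.
Growth never annexes another region's voxels — it is constrained assistance,
in contrast to the authoritative brush. For shrinking, depth (distance to
the slice's non-region complement) replaces distance, the intensity rule
flips to `<= t`, and removal proceeds from the region's in-plane boundary
through the eligible set, so dim interior voxels shielded by brighter ones,
or deeper than the selection, are retained. Two readings of "no farther than
the selected voxel" were possible — distance to the nearest region voxel or
to the region boundary; this package uses the nearest region voxel in-plane,
which makes `d*` well-defined even for selections far from convex regions.
Growing at a brighter voxel always yields a subset of growing at a dimmer
one at the same location, which the tests check as a property.

**Merge.** Reassigns every voxel of the source label to the target: total
labeled voxels are conserved and the region count drops by exactly one.

## The split algorithm

Fused nuclei are the hardest routine error. The algorithm exploits the fact
that stained nuclei are brightest toward their centers, so a rising
threshold inside the fused region eventually separates them:

1. **Sweep.** Candidate thresholds are the region's *distinct intensity
   values*, ascending — exact and resolution-independent, with no step-size
   parameter. At each candidate `t` the mask `{v in region :
   intensity(v) >= t}` is decomposed into connected components.
2. **Seed selection.** Among candidates yielding exactly `n` components
   (`n` supplied by the user after visual inspection), the candidate
   maximizing the volume of the *smallest* component wins; ties go to the
   lowest threshold. Maximizing the minimum volume avoids seeds that are
   noise specks. The selection criterion is generalized from the 3-nuclei
   case to any `n >= 2`. If no candidate yields exactly `n` components —
   e.g. a constant-intensity region — the split is infeasible, reported as
   an error with the volume unchanged.
3. **Growth.** The working intensity steps down through the region's
   distinct values from the seed threshold to the region minimum. Each step
   is a single simultaneous 1-voxel dilation of all seeds (under the module
   connectivity) into unclaimed region voxels at or above the working
   intensity. When two seeds reach a voxel in the same step, it goes to the
   seed whose claiming neighbor is brightest, ties to the lowest seed index
   — deterministic, and favoring the more confident front. At the minimum
   intensity, dilation repeats until a full pass changes nothing.

For a connected source region the growth phase provably claims every voxel
(each unclaimed voxel eventually has a claimed neighbor at the minimum
intensity), so the new regions partition the source exactly and merging them
back restores it bit for bit — both are tested invariants. A disconnected
source region (possible after manual edits) can leave voxels unreachable
from every seed; these are set to background with a warning and counted in
`unassigned_count`, rather than silently left under a label the user
believes was split. Voxels outside the source region are never touched.

After a split, the largest seed keeps the source label and the others
receive fresh labels above the current maximum — stable bookkeeping for the
region table and sidecar.

## Region bookkeeping

The region table (`build_region_table()`) derives sizes and tight bounding
boxes from the label volume itself, so it can never drift from the data;
only the `modified`/`done` flags live outside, in a JSON sidecar
(`{"version": 1, "regions": {"<label>": {"modified": ..., "done": ...}}}`,
unknown keys preserved). The schema is this package's own dialect — no
published schema exists for such sidecars. Editing operations record the
labels they touch on the volume (`modified_labels()`), and
`update_metadata()` folds those into the sidecar and drops entries for
labels that no longer exist; entries for absent labels found on *load* are
kept but flagged stale, with a warning, since they may indicate a sidecar
from an older segmentation version.

## Metrics and statistics

The reliability gate compares whole segmentations between raters, so Dice
is computed on the binarized foreground; an instance-matched per-region
variant exists (`dice(..., per_region = TRUE)`) but is informational. Both
masks empty scores 1 by convention. The gate passes iff Dice `>= 0.85` and
region counts agree within ± 1 — both thresholds are arguments.

`paired_t_test()` wraps the standard two-tailed paired t-test with 95%
Student-t confidence intervals, plus the means, mean difference, and percent
reduction (`100 (m_a - m_b) / m_a`, reported to one decimal). Zero-variance
differences, which make the standard test undefined, are handled explicitly:
all-zero differences give `t = NaN`, `p = 1`; a constant nonzero difference
gives `t = ±Inf`, `p = 0`, and a degenerate interval. P-values are reported
to five significant figures and no multiple-testing correction is applied.

## Synthetic scenes

The generator exists so that every algorithm is testable, end to end,
without any real image. A nucleus is an axis-aligned anisotropic Gaussian
intensity profile — chosen over hard ellipsoids precisely so that the split
algorithm's premise, brighter centers, holds by construction. Defaults:
nominal radii `(5, 4.5, 4.5)` μm (axial extent consistent with a nucleus
spanning roughly five 2.5 μm slices), peak intensity 200 over background
mean 10 with additive Gaussian noise of sd 5 (clipped at zero, rounded to
integer counts), falloff sigma 0.5 of the nominal radius. Ground-truth
membership uses the cutoff `0.5 × (profile at the nominal radius)` — some
cutoff is required to bound a Gaussian's support, and this one keeps the
ground-truth nucleus slightly larger than its nominal radius; it is a
documented constant of the generator. The voxel's label is the nucleus with
the largest normalized profile above its cutoff.

`make_touching_cluster()` places k ∈ {2, 3} nuclei with pairwise center
distance `(1 − overlap) × (sum of in-plane radii)`, rotated in-plane and
jittered ~10% in radius and peak under the seed, producing regions that fuse
under a global threshold while the ground truth keeps them distinct — the
canonical split fixture. `make_cortex_block()` draws a Poisson number of
nuclei at a target density (default ≈ 460 nuclei per 96 × 96 × 160 μm,
typical of adult mouse cortex) with uniform random centers; the default
extent is a one-eighth-volume block so tests render in seconds.

What the generator does *not* emulate: light-sheet point-spread functions,
stripe artifacts, vignetting, Poisson shot noise, chromatic channels, or
non-Gaussian nuclear textures. Passing tests on synthetic clusters therefore
demonstrate the algorithms' correctness and their behavior under the stated
intensity model — not segmentation accuracy on real tissue, where boundary
ambiguity and imaging artifacts dominate.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations to run in
seconds on one core: component-labeling checks against an independent
graph-components oracle use 100 random volumes up to 16³ voxels; split seed
selection is checked against exhaustive threshold search on 50 random
regions up to 12³; split recovery uses 20 seeded touching-cluster fixtures
each for k = 2 and k = 3, asking that at least 90% of every ground-truth
nucleus's voxels land in a single output region.

Numerical conventions worth stating: intensity comparisons in the sweep are
exact (the candidates are the data's own values, so no tolerance is
involved); TIFF integer storage uses the smallest of 8/16-bit unsigned
widths that holds the maximum value, and floating-point TIFF is limited to
`[0, 1]` 32-bit samples (arbitrary floats belong in NIfTI); all generator
randomness is drawn under an isolated RNG state, so rendering a scene never
perturbs the caller's random stream.

## Known limitations

* Volumes are held in memory; there is no chunked or lazy loading.
* Grow/shrink are strictly in-plane by design; there is no 3D brush.
* The split sweep is exhaustive over distinct intensities, which is exact
  but can be slow for very large regions with continuous-valued intensities
  (real microscopy data is integer-valued, keeping candidates bounded).
* The per-region Dice variant uses greedy largest-overlap matching, not
  optimal assignment.
* No undo stack: operations return new label volumes, so callers keep
  history by keeping references.
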