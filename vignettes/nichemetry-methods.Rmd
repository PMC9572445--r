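---
title: "Quantifying cell packing and motility in graded wall-and-niche microscaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell packing and motility in graded wall-and-niche microscaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemetry)
```

## The measurement problem

Microfabricated polymer scaffolds built as arrays of thin vertical walls act
as "micro-rulers" for cell biology: when wall separations and niche (pocket)
sizes are systematically graded across one structure, the spatial
distribution and motility of seeded cells can be read off directly as a
function of geometry. Two obstacles stand between the raw confocal data and
those numbers:

1. the photopolymer autofluoresces across the whole visible range, swamping
   the stain signal of the cells, and
2. "how strongly do cells hug the walls" needs a null model — the fraction
   of signal expected near the walls if cells ignored the scaffold
   entirely.

`nichemetry` implements the full chain: a parametric scaffold geometry with
closed-form expectations, spectrally resolved (lambda-mode) image
generation with known ground truth, per-voxel linear unmixing to separate
scaffold from cell fluorescence, per-chamber packing statistics against the
isotropic expectation, and a radius-kernel nucleus tracker that produces
motility gradient maps.

## Scaffold geometry

A unit wall is 210 µm long and 24 µm tall, subdivided by 15 µm cross walls
into sections of 10, 10, 10, 30, 30, 50 and 70 µm; the pockets on either
side of the wall between consecutive cross walls are the *niches*. Four
units joined end-to-end (the second pair mirrored, so sizes ramp up and
jump back) give an 840 µm wall. Sixteen such walls stand in four sets of
four with separations of 20, 25, 35 and 55 µm, spanning 840 × 520 × 24 µm³
(≈ 1.05 × 10⁷ µm³). Two parallel walls plus one niche section bound a
*chamber*; its footprint is `niche_size × wall_separation` (200 µm² for
10 × 20 up to 3850 µm² for 70 × 55) and its end opening is
`wall_separation − 15` µm (5 to 40 µm).

All dimensions follow the centre-of-traced-line convention; the fabricated
line thickness (2 µm) is carried separately and reduces effective niche
sizes by about one thickness. Geometry functions report design dimensions,
matching how the printed design values are quoted; the rasterizer draws
material at full thickness.

Two conventions were genuinely open and are fixed here as package choices:

* the in-wall **order** of niche sections is `[10, 10, 10, 30, 30, 50, 70]`
  (only the counts are dictated by the design); it is configurable;
* the overall 520 µm depth exceeds the twelve in-set wall gaps (405 µm); the
  remaining 115 µm is split equally over the three gaps **between** sets
  (≈ 38.3 µm each). Both are parameters of `scaffold_params()`.

A *chamber* row in the model refers to one (set, gap, section) class; the
four structural repeats of that section along the 840 µm wall are recorded
as replicate rectangles of the same chamber and pooled in the statistics.

The key null model is the isotropic niche-occupancy ratio: for material
spread uniformly over a chamber, the expected fraction within
`niche_depth = 7.5` µm of either bounding wall is

```{r}
isotropic_niche_ratio(c(20, 25, 35, 55), niche_depth = 7.5)
```

i.e. `min(1, 2 * 7.5 / separation)` — 0.75, 0.60, 0.43 and 0.27 after
rounding. Separations at or below twice the niche depth saturate at 1.

## Synthetic image generation

No public image data accompany this design, so the generator is a
first-class, tested module that emulates the acquisition: 12 Z slices at
2 µm over the 24 µm walls, a 630 × 520 µm field at 1.66 µm/px, and
lambda-mode detection with 32 channels spanning 416–687 nm (405 nm
excitation) or 23 channels spanning 494–687 nm (488 nm excitation). Channel
centres sit on an even grid between the printed endpoints (≈ 8.7 nm
spacing, nominal 9 nm bins).

Four emitters are modelled, each with a unit-sum spectrum: broad sloped
scaffold autofluorescence, a Hoechst-like nucleus stain (Gaussian, peak
460 nm, FWHM 50 nm), a CF488-like cytoplasm stain (peak 515 nm, FWHM
40 nm), and a flat background. The stain shapes are generator conventions
with known ground truth, not claims about the real dyes. Scaffold
brightness follows the UV-quench model below and defaults to five times the
unit cell brightness after 150 min of treatment.

Cells are spheres (diameter 15 µm, nucleus 8 µm, the average for this cell
line) whose per-voxel abundance is the column length of the sphere through
each 2 µm slab. Mass that would fall on wall material is redistributed over
the cell's remaining voxels: cells deform against the solid walls rather
than interpenetrate them, and their fluorophore content is conserved. This
keeps the rendered data consistent with the model's own assumption that
cells never cross walls.

Noise is Poisson shot noise on a detected-count scale (default 5000 counts
per unit abundance, typical of a 16-bit confocal detector at these
intensities) plus Gaussian read noise (sd 2 counts). Every stochastic step
flows from one seed; identical configuration and seed give bit-identical
output.

Time-lapse sequences use 6 timepoints at 65 min (5 h 25 min total), a
confined random walk with mean per-interval displacement `step_scale`
(default 5 µm, chosen so typical 5-interval totals fall in the 0–30 µm
range that motility maps of such scaffolds display), reflection off wall
material, and no vertical motion. Seeding density defaults to the sparse
regime used for tracking studies.

What the generator deliberately does **not** emulate: optical point-spread
and confocal sectioning physics, cell division, death or deformation
beyond wall clipping, excitation crosstalk between the two stacks, and
stage drift (alignment is exercised by injecting shifts). Tests passing on
this phantom therefore validate the *analysis* chain, not microscope
physics.

## Spectral unmixing

Endmember spectra are estimated as unit-sum mean spectra over user ROIs
(`estimate_endmembers()`), exactly as the manual-ROI step of commercial
lambda-mode unmixing; near-identical ROI spectra raise an
ill-conditioning warning. Per voxel, `unmix()` solves
`min ‖E a − y‖₂`, unconstrained (`ols`) or with `a ≥ 0` (`nnls`, the
default — abundances are material amounts). The NNLS solution is computed
exactly: a fast path solves on the positive support of the unconstrained
solution and accepts it when the KKT conditions hold; remaining voxels
fall back to enumerating all active supports — with at most a handful of
endmembers, every support's restricted least-squares solution can be
checked for feasibility, and the feasible one with minimal residual is the
optimum. This is implemented in compiled code and vectorised over voxels;
voxels are fully independent, and no spatial regularisation is applied.
Because endmember spectra are unit-sum, abundances carry the intensity
units of the data; background is a fourth endmember rather than a
subtraction.

`masked_views()` zeroes wall pixels in the cell abundance maps (the
polymer cannot contain cells) while retaining the scaffold abundance as a
position marker.

## Packing statistics

`sum_per_chamber()` sums cell abundance per chamber over the full stack
height, assigning pixels by pixel centre and excluding wall-material
pixels from both numerator and denominator. Densities are normalized to
the smallest chamber footprint (200 µm²); `niche_ratio` is the fraction of
a chamber's abundance inside the 7.5 µm contact zone, compared against the
isotropic expectation (`compare_to_isotropic()`, `aggregate_packing()`).

Three numerical facts matter when interpreting recovered ratios at the
acquisition resolution:

* the *occupiable* contact zone is 6.5 µm per side, not 7.5 — the wall
  band itself (±1 µm) is excluded — so even perfectly uniform material
  yields ratios slightly below `2 × 7.5 / separation`;
* nuclei are extended 8 µm emitters: material seeded entirely inside the
  zone still spills part of its rendered mass beyond the 7.5 µm line, so
  intensity-weighted ratios cannot reach 1 even at full niche bias;
* the 1.66 µm grid quantizes the zone boundary by up to ±0.8 µm.

These are properties of any intensity-based contact measurement at this
resolution, and they are visible in the package's own acceptance runs: at
zero bias the recovered ratios track the isotropic curve to a few
hundredths, while strongly biased seedings are compressed toward the wall
side of the scale.

## UV-quench model

Scaffold autofluorescence under UV treatment follows
`I(t) = I0 · exp(−k t)`. `fit_quench()` fits the line in log space —
mirroring the log-scale linearity of such bleaching curves and giving a
closed-form, testable estimator — and recovers noiseless parameters to
relative 1e-6. The default rate is calibrated so that 22% of the initial
intensity remains after 150 min (`quench_rate(0.22, 150)` ≈ 0.0101 min⁻¹).

## Nucleus tracking

Stacks are split at 14 µm: bottom 7 slices (one average cell height above
the substrate) and top 5 slices, each max-projected (mean projection is
available; maximum is the default because nuclei are compact bright
objects). `detect_nuclei()` smooths, thresholds (Otsu), filters connected
components by an area window derived from the nominal nucleus size, and
returns intensity-weighted centroids.

`link_tracks()` implements radius-kernel greedy linking: the kernel `N`
(default 10 px = 16.6 µm at 1.66 µm/px, about one cell diameter) is the
radius within which a track must find a nucleus at the next timepoint; the
nearest unclaimed detection is taken, ties break to the lowest detection
index, and claims are exclusive. Tracks are grown one at a time in seeding
order (deterministic); a second pass re-seeds from detections not claimed
in the first, recovering cells that enter later; tracks spanning fewer
than 5 of the 6 timepoints are discarded. The maximum step bound makes
`(n_timepoints − 1) × N × pixel_size` = 83 µm the largest representable
total path at defaults. On configurations where all cells stay more than
`2N` apart, greedy linking provably coincides with the exhaustive
minimum-total-distance assignment, which the tests verify against a
brute-force oracle.

`render_gradient_map()` deposits each track's total distance as a Gaussian
bump (sigma 5 px — wide enough to be visible at the map scale, narrow
enough to stay local; only field maxima are asserted in tests, not bump
shapes) around its positions, combines overlaps by maximum, and clips at a
display ceiling of 30 µm. `summarize_motility()` groups tracks by the
wall-separation region of their first position (or "control" outside the
wall sets) and reports counts, mean/max totals and niche fractions.

## Problem sizes and determinism

The shipped tests generate every fixture in code. Full-chain checks run on
the complete 630 × 520 µm field (380 × 314 px, 12 slices, 32 channels) with
200 cells and 10 seeds per condition for packing recovery, a 128 × 128 × 12
× 32 stack for the unmixing error budget, and 20 seeds of 60-cell
time-lapses for the seeding statistics; unit tests use one- or two-set
scaffolds at coarser grids. All random draws pass through a single
`with_seed()` gate, and rebuilding any object from the same configuration
and seed is bit-reproducible.

## Known limitations

* Absolute intensity units are arbitrary; only geometric expectations,
  recovery errors and trends are meaningful.
* The extended-emitter compression of niche ratios (above) means
  intensity-weighted contact fractions are conservative for strongly
  wall-attached populations.
* Greedy linking can mis-assign when cells approach within the kernel
  radius of each other; no probabilistic or motion-model linking is
  provided, and vertical (Z) motion is not tracked.
* The rasterizer is binary at pixel resolution; per-structure areas carry
  a one-pixel quantization that the convergence tests bound.
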