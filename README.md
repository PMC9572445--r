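# nichemetry

Analysis toolkit for **graded wall-and-niche microscaffold cultures**:
quantifying how the geometry of a microfabricated polymer scaffold — wall
separations and niche (pocket) sizes graded across one structure — shapes
the packing and motility of seeded cells imaged by spectrally resolved
confocal microscopy.

The package is aimed at microscopists and tissue-engineering groups who
use thin-walled photopolymer scaffolds as "micro-rulers": structures whose
systematically varied dimensions let cell behaviour be read out directly
as a function of geometry. It provides the full analysis chain plus a
synthetic-data generator with known ground truth, so every stage is
testable end to end without proprietary microscope files.

## What it computes

**Geometry and null model.** A parametric scaffold model (unit walls of
210 µm subdivided into 10/10/10/30/30/50/70 µm niche sections by 15 µm
cross walls; 16 walls in sets at 20/25/35/55 µm separations; 840 × 520 ×
24 µm³ bounding volume) with closed-form chamber footprints
(`niche × separation`, 200–3850 µm²), end openings (`separation − 15`,
5–40 µm), and the isotropic niche-occupancy ratio

```
r_iso(s) = min(1, 2 d / s),   d = 7.5 µm (niche depth), s = wall separation
```

— the fraction of uniformly distributed material expected within 7.5 µm
of the walls, i.e. the baseline for detecting wall-contact enrichment
(0.75, 0.60, 0.43, 0.27 for the four separations).

**Spectral linear unmixing.** Per-voxel least squares `min ‖E a − y‖₂`
(optionally `a ≥ 0`, solved exactly by active-support enumeration in
compiled code) decomposes lambda-mode stacks (32 channels at 405 nm
excitation, 23 at 488 nm) into scaffold-autofluorescence, nucleus-stain,
cytoplasm-stain and background abundances, with ROI-based endmember
estimation and wall masking.

**Packing statistics.** Per-chamber abundance totals over the full stack
height, densities normalized to the 200 µm² reference chamber, and niche
ratios compared against `r_iso`.

**UV-quench model.** Single-exponential bleaching `I(t) = I0 e^{−kt}` of
scaffold autofluorescence with a log-linear fit; the default rate leaves
22% after 150 min.

**Nucleus tracking.** Z-partition projections (bottom 7 / top 5 slices),
blob detection, radius-kernel greedy nearest-neighbour linking
(`N = 10 px = 16.6 µm`, two passes, 5-of-6-timepoint minimum), total path
lengths, motility gradient maps and per-region summaries.

## Worked example

```r
library(nichemetry)

chamber_footprint(10, 20)              # 200  (smallest chamber, um^2)
chamber_footprint(70, 55)              # 3850 (largest chamber, um^2)
isotropic_niche_ratio(c(20, 25, 35, 55))
# 0.7500000 0.6000000 0.4285714 0.2727273

build_scaffold()
# scaffold_model: 16 walls of 840 um, 84 chambers
#   bounding box: 840 x 520 x 24 um = 10,483,200 um^3
#   separations: 20, 25, 35, 55 um; niche sections: 10, 10, 10, 30, 30, 50, 70 um
```

A reduced synthetic experiment — two wall pairs (20 and 55 µm), 40 cells
seeded half-and-half between niche zones and chamber interiors, rendered,
unmixed and packed:

```r
m  <- build_scaffold(scaffold_params(n_sets = 2, walls_per_set = 2,
                                     units_per_wall = 1,
                                     wall_separations = c(20, 55),
                                     total_depth = NULL))
im   <- imaging_config(fov = c(212, 134))
mask <- rasterize_scaffold(m, im$pixel_size,
                           width = im$nx * im$pixel_size,
                           height = im$ny * im$pixel_size)
cells <- place_cells(m, 40, niche_bias = 0.5, seed = 7)
stack <- render_stack(m, cells, default_endmembers(), im, seed = 7, mask = mask)
# hyperspectral_stack: 12 slices x 32 channels x 81 x 128 px (exc. 405 nm, 1.66 um/px)

ab <- masked_views(unmix(stack, default_endmembers(), mode = "nnls"), mask)
aggregate_packing(sum_per_chamber(ab, m, mask, endmembers = "nuclei"))
#   wall_separation endmember niche_ratio isotropic_ratio density_per_unit_area
# 1              20    nuclei       0.863           0.750                  23.0
# 2              55    nuclei       0.391           0.273                  24.6
```

Half the cells were seeded in contact with the walls, and the recovered
niche ratios sit correspondingly above the isotropic baseline in both
separation classes — strongly so in the narrow chambers, where even
uniform material is mostly near a wall. Tracking the same population over
six timepoints (65 min apart):

```r
tl    <- simulate_timelapse(m, cells, motion_spec(step_scale = 5), im, seed = 7)
dets  <- lapply(tl$frames, function(f)
  detect_nuclei(z_partition(f, bottom_slices = 7)$bottom,
                pixel_size = im$pixel_size))
tracks <- link_tracks(dets, tracking_config(N = 10, pixel_size = im$pixel_size))
# track_set: 29 tracks (N = 10 px, min 5 points)
#   total distance: 11.4 - 38.4 um

summarize_motility(tracks, m, mask)
#   region n_tracks mean_total_um max_total_um niche_fraction
# 1     20       10          21.3         38.4          0.900
# 2     55       19          25.0         36.9          0.421

map <- render_gradient_map(tracks, dim(mask$grid), mask, display_max = 30)
plot(map)   # blue = stationary, red = highly motile, walls overlaid
```

## Further reading

The methods vignette (`vignettes/nichemetry-methods.Rmd`) documents the
geometry conventions, the generator's emitters and noise model, the
unmixing solver, the packing and tracking conventions, the numerical
choices behind them, and the known limitations of intensity-based contact
measurements at the 1.66 µm acquisition scale.
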