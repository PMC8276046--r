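# rootascent

Automated phenotyping of root system architecture (RSA) from 2D rhizotron
scans, for plants propagated by cuttings — grapevine being the motivating
case. Cuttings form **adventitious roots** from the stem, off which
**lateral roots** branch; separating the two automatically is the hard part
of quantifying RSA, and is what this package does. A companion module
quantifies root volume in reconstructed neutron-tomography stacks of
sand-grown cuttings.

## Who this is for

Root biologists and phenotyping platforms that scan flat rhizotrons
(two overlapping scanner passes per device, typically 300 dpi) or image
root systems photographically, and need per-root architectural traits over
time without manual tracing.

## The method

The pipeline is a four-stage image analysis around a skeleton-traversal
algorithm (the *ascending path*):

1. **Stitching.** The two scan halves are merged by corner-keypoint
   matching and a RANSAC-estimated homography `H` (bottom-half → top-half
   coordinates), then blended on the union canvas (per-pixel average in
   the common band).
2. **Segmentation.** Otsu's threshold `t* = argmax_t σ²_B(t)` — the split
   of the gray histogram maximizing between-class variance — gives the
   binary root mask (roots white on dark background; polarity
   configurable). Connected components below `min_object_px` are dropped.
3. **Skeletonization and point classification.** Homotopic thinning erodes
   the mask to a 1-px skeleton deleting only simple points (topology
   preserved: component and hole counts are invariant). Each skeleton
   pixel is classified from the cyclic change count over its
   8-neighbourhood `P1..P8`,
   `C = Σ_i [P_i ≠ P_(i+1)]`: `C = 0` isolated, `C = 2` endpoint,
   `C = 4` normal point, `C ≥ 6` junction (≥ 3 branches).
4. **Ascending path and reconstruction.** From the lowest skeleton pixel
   (root tip) the traversal walks upward, at each junction probing every
   branch `L` pixels ahead and taking the most ascending one, backtracking
   from dead ends, until the highest pixel (stem base). This isolates the
   adventitious-root skeleton. Left/right radii scanned from each path
   pixel to the mask boundary give the local diameter
   `d(i) = r_left(i) + r_right(i) + 1`; bulges in the radius profile above
   a running-median baseline (thresholds Th1/Th2) are detected as lateral
   roots or nodules, classified by peak height, width and area, and
   suppressed with an iterated band-limited filter — yielding the
   adventitious root alone, at its own diameter.

Traits per adventitious root: ARL (root length, mm), DIA (local diameter
profile; mean and apical summaries), LRN (lateral count), LLRL (longest
lateral root length), TNN/PNN (nodule counts, optional), projected root
area, ARN (adventitious root count per image), and growth series across
acquisitions. For tomography stacks: open-beam normalization of
radiographs, stack binarization, and RSV (root system volume) from voxel
counts.

Everything is testable without plant data: `render_root()` /
`render_tomo_stack()` generate synthetic root images and transmission
stacks with exact ground truth (masks, centrelines, width profiles, trait
values).

## Worked example

```r
library(rootascent)

spec <- fixture_specs("sparse_lateral")[[1]]   # 400x300 px, 3 laterals
r <- render_root(spec)                          # image + ground truth
res <- run_pipeline(r$image, pipeline_config())

res$mask
#> binary_mask: 400 x 300 px, 2639 foreground (2.20%), polarity bright
res$skeleton_graph
#> skeleton_graph: 494 px, 1 component(s) [endpoint=5, junction=3, normal=486]
round(res$traits[, c("arn", "arl_mm", "dia_mean_mm", "projected_area_mm2",
                     "lrn", "llrl_mm")], 3)
#>   arn arl_mm dia_mean_mm projected_area_mm2 lrn llrl_mm
#> 1   1 30.742       0.515             18.918   3   4.528
```

Reading the numbers: one adventitious root (`arn`) of 30.7 mm (truth:
30.5 mm) with mean local diameter 0.515 mm; projected root area 18.918 mm²
(equal to the ground truth, the mask being recovered exactly on a
noiseless image); all 3 laterals found (`lrn`), the longest 4.53 mm
(truth 4.66 mm). `run_pipeline(..., out_dir = "out/")` additionally writes
`traits.csv`, per-stage rasters and a QC overlay. A command-line front end
for every stage is in `inst/cli/rootascent.R`.

## Scope and limits

The package consumes reconstructed tomography stacks (tomographic
reconstruction itself, e.g. filtered back-projection, is done upstream);
it does not model growth, predict biomass from area, or extract 3D
architecture graphs. The methods vignette
(`vignettes/ascending-path-methods.Rmd`) documents the model, every
tunable parameter, the synthetic generator's scope, and known limitations.
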