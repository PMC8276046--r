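---
title: "Ascending-path root phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ascending-path root phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootascent)
```

This vignette is the package's own account of its methods: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

## The problem

Plants propagated by cuttings (grapevine, many perennials) root
adventitiously: main roots emerge from the stem and laterals branch off
them. In a flat rhizotron the root system grows in a quasi-2D plane and
can be scanned repeatedly, but a scan shows one tangled binary shape;
the quantity of interest — per-adventitious-root length, diameter profile,
lateral counts — requires separating each adventitious root from its
laterals automatically. The package's core is a skeleton-traversal
algorithm exploiting the one strong prior of this system: adventitious
roots run predominantly downward, so walking the skeleton from its lowest
point upward and always preferring the ascending branch recovers the
adventitious root and leaves the laterals behind.

## Pipeline stages and their assumptions

### Stitching

Rhizotrons are larger than flatbed scanners, so each device is scanned in
two overlapping halves. `estimate_alignment()` detects Harris corners on
the luminance of both halves, matches normalized 15×15 intensity-patch
descriptors (mutual nearest neighbour, correlation ≥ 0.6), and estimates
the homography bottom→top by RANSAC (4-point normalized DLT samples,
reprojection tolerance 2 px, 1000 iterations, fixed seed) followed by two
least-squares refits on the consensus set. The contract is the output
accuracy — mean inlier reprojection error, which the acceptance suite
bounds at 1 px on warped synthetic splits — not the detector brand; any
detector satisfying the bound would do, and patch descriptors suffice
because the two passes of one scanner differ by a near-rigid transform
with mild perspective (no scale change). `merge_halves()` composes the
union canvas and averages the two halves in the common band: averaging
avoids a visible seam and, because the band is imaged twice by the same
sensor, there is no exposure mismatch to equalize. Assumption: the common
band contains texture (roots, substrate grain, membrane weave). A
uniformly black band yields "insufficient keypoints" — by design, since
any alignment would then be unverifiable.

### Segmentation

Otsu's threshold is computed exactly (argmax of between-class variance
over all 255 split points of the 8-bit histogram; ties to the smallest
level). The assumption is a bimodal histogram — bright roots on a dark
background — which holds for scans of white young roots on dark substrate
membranes. `polarity` exists for inverted setups; `"auto"` maps the
brighter class to roots. `min_object_px` (default 20 px at 300 dpi,
i.e. ~0.14 mm²) removes debris and is off-able; it is an addition to the
threshold-then-skeletonize chain, justified because real scans carry
perlite specks and condensation droplets. No despeckling precedes
thresholding; on noisy inputs the component filter plays that role.

### Skeletonization and point classes

Thinning deletes only (8,4)-simple points — pixels whose removal changes
neither the 8-connected foreground components nor the 4-connected holes —
in four directional sub-iterations (north, south, east, west borders) with
a deterministic raster order. Simplicity is decided by two lookup tables
over the 256 neighbour configurations (T8 = foreground components in the
punctured neighbourhood, T4b = background components touching a
4-neighbour), built once by brute-force union-find, so the implementation
is verifiable against its definition. Two details matter:

* **Two-phase sub-iterations.** Within one directional pass, candidates
  are marked first and then deleted sequentially. Deleting while scanning
  would let deletions cascade through a whole layer in one pass (the
  west pass would eat a root from the left edge rightwards), biasing the
  skeleton off-centre by several pixels.
* **Stub pruning.** Endpoint protection (pixels with one neighbour are
  never deleted) preserves branch lengths but can freeze 1–2 px boundary
  bumps into branch stubs. `skeletonize()` therefore removes endpoint
  stubs of ≤ `prune_px` (default 2) pixels that terminate at a junction,
  then re-thins. Stub removal is itself a sequence of simple-point
  deletions, so topology is still preserved; 2 px is far below any lateral
  root (laterals shorter than `min_lateral_px = 10` px are not counted
  anyway), so this cleans artifacts without pruning biology.

Every skeleton pixel is classified by the cyclic change count `C` of its
8-neighbourhood: isolated (0), endpoint (2), normal (4), junction (≥ 6).
`C = 2` also covers tips whose two active neighbours are mutually
adjacent — the natural generalization of "endpoint" for digital root tips,
taken here as the normative reading since only pictorial examples exist
for those patterns. The classification is a pure function of the raster
and is tested exhaustively against an independent run-count oracle on all
256 configurations.

### The ascending path

Anchors are forced by definition: start = lowest active pixel, breakpoint
= highest (ties to the smallest column, documented). The walk marks pixels
visited; at a junction each unvisited branch is probed `lookahead` pixels
ahead (default `L = 15`) and the branch whose probe ends highest wins.
A 1-px "which neighbour is higher" decision would be hostage to skeleton
jitter; 15 px ≈ 1.3 mm at 300 dpi is long enough to average out jitter and
short enough that a lateral's initial descent is still visible. Ties break
by smaller column deviation from the current heading, then smaller column
— deterministic. Dead ends (an endpoint that is not the breakpoint)
trigger depth-first backtracking to the last junction, making the
traversal total on trees: on a tree-shaped skeleton the result is exactly
the unique tip-to-top path regardless of decoy branches, which is why the
suite checks it against a brute-force shortest-path oracle. On skeletons
with loops (overlapping roots) the traversal remains defined but may
exhaust all branches ("no ascending route"); loops are permitted in
classification and tracing but geodesic uniqueness is no longer
guaranteed.

Images with several adventitious roots are handled per 8-connected
skeleton component (`trace_all_components()`, one root per component,
components under `min_component_px = 30` px skipped). ARN is the number of
traced components. Splitting several adventitious roots that share one
component is not attempted — nothing in the change-count machinery
distinguishes "two fused adventitious roots" from "root plus thick
lateral" without growth history.

### Radius profile, peaks, reconstruction

From each path pixel the mask is scanned to the boundary on both sides,
perpendicular to the local tangent (estimated over ±2 path steps). The
scan is quantized to the raster axis nearer the perpendicular: horizontal
for near-vertical segments — the usual case for an adventitious root, and
the natural "left/right of the root" cut — vertical for near-horizontal
ones. Diagonal scan lines were rejected deliberately: a diagonal pixel
count measures physical width in units of √2 px and under-reports
diameters by up to 30%, whereas an axis-aligned chord is an exact pixel
count whose meaning ("width of the root in this row") is unambiguous at
any tilt below 45°. The cost is a cos θ inflation of the chord on tilted
segments, ≤ 8% below 22° of tilt; adventitious roots in rhizotrons rarely
tilt more.

Each side's radius sequence is compared to a running-median baseline
(window 31 positions ≈ 2.6 mm; the median is robust to the ≤ 5-position
bumps a lateral produces). The baseline is estimated **once, from the raw
profile** — re-estimating it from partially filtered radii would let each
filter pass erode the root's genuine width variation. A maximal run with
`radius > baseline + Th1` that reaches the upper threshold Th2 is a peak;
`Th1 = 1` px (the boundary-scan accuracy — anything smaller is
unresolvable), `Th2 = baseline + 3·MAD(radius − baseline)` (scales with
profile noise; collapses to Th1 on noiseless profiles). Peaks are
classified from three parameters — height, width, area: laterals are
narrow and tall (width ≤ 12 px, height ≥ 3 px at 300 dpi), nodules wide
and voluminous (width > 12 px, area ≥ 40 px²). These cutoffs have no
published values; they were fixed once against the synthetic generator's
geometry (3-px laterals, 8–12 px nodule semi-axes) and are exposed in
`peak_params()`.

Suppression replaces radii inside each above-threshold run with the
baseline clamped into `[baseline − Th1, baseline + Th1]` — a band-limited
fill between the two thresholds — and iterates detection until no run
remains (cap `max_iter = 10`, warning on non-convergence). The
reconstructed adventitious mask is the union of per-position cross-section
segments of length `r_left + 1 + r_right` (filtered radii); the diameter
profile `d(i) = r_left(i) + r_right(i) + 1` converts to mm via
`mm_per_px`.

Note the division of labour: the **raw** radii carry the 1-px diameter
accuracy (they are what the diameter benchmark and the acceptance script
measure); the **filtered** radii carry the lateral-free reconstruction.
Suppression deliberately flattens any short width excursion above the
band, including rare genuine ones (e.g. at a curvature apex), because at
detection time a +2 px bump over three positions is indistinguishable from
a small lateral base.

### Traits

ARL is measured with a chord-subsampled estimator: the Euclidean lengths
of chords between every 4th path pixel. The naive per-step sum (1 per
direct, √2 per diagonal step) systematically overestimates slanted digital
curves — up to +8% at 22.5°, enough to matter on curved trunks — while
chord subsampling is exact on straight and 45° digital lines and unbiased
in between; `pixel_count = TRUE` restores plain pixel counting for
comparability with counting-based tools. Lateral lengths (tip-to-
attachment geodesics over the residual skeleton components touching the
path) use Kulpa's corrected step weights (0.948, 1.343) for the same
reason. LRN counts residual components at least `min_lateral_px = 10` px
long; LLRL is the longest lateral length. "LLRL" is expanded here as
*longest lateral root length* and TNN/PNN as *total / on-primary nodule
number* — interpretations, flagged as such, since the acronyms have no
canonical expansion; nodule traits are biologically void for grapevine and
exist for generality (two-sided nodule peaks with overlapping spans merge
into one nodule; only on-path nodules are seen, so PNN = TNN here).
The apical diameter averages the `apical_k = 20` tip-side positions of the
diameter profile, and the unbranched apical zone is the path length from
the tip to the first lateral peak. `growth_series()` orders trait records
by timestamp, inserts flagged rows for timepoints missing from the regular
grid (inferred from the smallest spacing), never interpolates, and
computes area ratios between consecutive present records.

### Tomography quantification

`preprocess_radiograph()` mirrors the standard radiograph cleanup chain:
3×3 median despeckle; replacement of any pixel deviating by more than 50
counts from the median over a radius-2 px disc (gamma-ray hits); division
by the pixel-wise mean open beam, giving transmission with mean 1 outside
the sample. `quantify_root_volume()` thresholds the reconstructed stack
(roots attenuate more than sand, so the root class is the
low-transmission side), with `"auto"` computing Otsu on the pooled,
256-bin stack histogram — an explicit, reproducible replacement for
manual contrast adjustment. RSV = voxel count × voxel edge³. An optional
26-connected size filter mirrors particle analysis (default off). Slices
are processed at full resolution; calibration is per voxel edge, so any
upstream rescaling must be reflected in `voxel_mm`.

## The synthetic generator

`render_root()` draws a spline trunk (control points top→tip, width
tapering linearly in arc length) by stamping discs at 0.5-px arc steps —
guaranteeing an 8-connected mask and an exact truth mask with no
anti-aliasing — then straight laterals at configurable branch positions,
sides, angles and lengths, then nodule ellipses; intensities are two-level
(background 30, root 200 by default, mimicking a dark membrane and white
roots) with optional Gaussian blur and noise, and every random draw is
fixed by the spec seed. Truth includes the trunk-only mask, the rasterized
centreline with realized per-row widths, lateral-only pixels, branch
points, and closed-form traits. The 12-name fixture suite
(`fixture_specs()`, stored as JSON) spans lateral-free, sparse/dense/steep
laterals, curved trunks, nodules, noise/blur, two roots and strong taper;
default geometry is a 400×300 px canvas (34×25 mm at the 300-dpi default
calibration) with trunks ~360 px long — sizes chosen so the full suite
exercises every code path in seconds while keeping ≥ 45 diameter samples
between branch zones.

What the generator does **not** emulate — and hence what green tests do
not certify on real scans: substrate texture and reflections, root hairs,
intensity gradients along a root, root overlaps (loops), curved laterals,
moisture films, and scanner vignetting. The two noisy fixtures cover
sensor noise and optical blur only. `render_tomo_stack()` likewise draws
constant-transmission sand (0.8) with uniform-random root-tube voxels in
[0.2, 0.4]; real stacks add beam hardening, rings and partial-volume
voxels that it does not model.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `[row, col]`, row 1 at top — the R-native
  equivalent of the raster convention; I/O transposes as needed.
* Otsu: ties resolve to the smallest threshold; constant images error
  ("degenerate histogram").
* Thinning treats out-of-image neighbours as background; empty masks pass
  through; classification rejects rasters with interior 2×2 blocks
  ("not a skeleton").
* Homography estimation refuses near-collinear samples and inlier sets
  ("degenerate geometry"); self-alignment returns identity to 1e-6.
  Merged canvas corners are rounded at 1e-6 before the bounding box so
  numeric jitter cannot inflate the canvas.
* `suppress_peaks` is monotone (area above baseline never grows) and its
  fill is idempotent against the fixed baseline, so the iteration cap is
  a formality except on adversarial profiles.
* Single-pixel components: start = breakpoint; the path has length 1 and
  zero ARL.
* Tomography: zero or negative mean open-beam pixels error ("zero open
  beam"); empty stacks error; the volume fraction is monotone in the
  threshold by construction.

## Problem sizes in the test suite

The suite renders 400×300 px fixtures (trunks ≈ 360 px), 20 warped
250×300 px stitching pairs, 64³–128³ voxel stacks, 50 random 64×64
topology masks and the full 256-configuration neighbourhood enumeration;
it completes in about half a minute on one core. These sizes are the
package's validation conditions: they are large enough that every
estimator operates in its asymptotic regime (e.g. ≥ 45 diameter samples
per branch-free zone, ≥ 100 RANSAC inliers per pair) and small enough to
keep the suite fast.

## Known limitations

* One adventitious root per skeleton component; fused root systems are
  returned as a single path.
* Diameters are axis-aligned chords; above ~30° of local tilt they
  overestimate the perpendicular width noticeably (cos θ factor).
* Lateral lengths are measured on the residual skeleton, which starts at
  the trunk's edge, so they under-report by roughly the trunk radius and
  blur extends them slightly on soft images.
* Peak classification cutoffs are resolution-bound (documented at
  300 dpi); other resolutions must rescale `peak_params()`.
* The stitcher assumes two tiles with a single overlap band; multi-tile
  mosaics, lens distortion and exposure correction are out of scope.
* Nodules on laterals are invisible to the radius profile of the main
  root; TNN counts on-primary nodules only.
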