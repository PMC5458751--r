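---
title: "Methods: chandelier-cell arbor morphometry and synapse-specificity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chandelier-cell arbor morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `chcmorph`. The package analyses the axonal organisation
of chandelier cells (ChCs): how many bifurcations and varicosities the
proximal arbor carries, which varicosities are apposed to axon initial
segments (AISs), which ones contain presynaptic marker, and how vesicle
shape and density differ between varicosity classes on electron
micrographs. Because the corresponding real imaging data are not publicly
available, the package ships a synthetic-data generator with exact ground
truth; all validation rests on recovery of known truth plus closed-form
identities.

## Coordinate conventions

All public coordinates are right-handed `(x, y, z)` in micrometres, with
`y` increasing toward deeper cortical layers (the soma sits at small `y`)
and `z` running through the slice. In memory, channels are stored as R
arrays `dim = c(ny, nx, nz)` — one image matrix per z-slice, matching how
`tiff::readTIFF` returns multi-page files — rather than the
`(z, y, x)` layout common in Python imaging stacks; the voxel size
carries the anisotropy (default 0.2 × 0.2 × 0.5 µm, a typical confocal
sampling at 63×). The analysis ROI is the 100 × 100 µm square directly
below the soma, spanning the full slice depth (60 µm by default).

## The synthetic stack generator

`generate_stack()` emulates a sparsely labelled layer-2 ChC:

* **Arbor**: a recursive bifurcating tree grown from the soma with
  downward bias and per-step direction jitter, with exactly
  `n_branch_points` bifurcations. A clearance constraint keeps
  non-adjacent branch centrelines ≥ 2.5 µm apart so distinct branches
  never fuse in the image. Each branch is grown at least 4.5 µm at
  creation, which makes every terminal branch and every inter-junction
  segment long enough to be resolvable. The first 8 µm of the primary
  axon are straight so the somatic exclusion mask (below) cuts it exactly
  once.
* **Cartridges and AISs**: a subset of terminal tips is extended into
  near-vertical (≤ 8° tilt) cartridge branches of the configured AIS
  length; an AnkG-like tube of radius `ais_width_um / 2` runs parallel at
  a lateral offset chosen so that varicosities on the cartridge branch
  sit ~0.2 µm from the tube surface — inside the 0.5 µm apposition
  tolerance. Tube axes are kept ≥ 7 µm apart so each AIS segments as one
  object and no varicosity is ambiguous between two tubes.
* **Varicosities**: Gaussian intensity bumps (FWHM = configured diameter,
  default 2.0 µm in x–y and 2.5 µm in z, both below the selection
  cutoffs) max-combined onto the shaft. The raw blob peak equals
  `varicosity_brightness_ratio` × the raw shaft peak so the measured
  peak-to-shaft ratio reproduces the configured one. AIS-class
  varicosities sit on cartridge branches (3 µm spacing); off-target sites
  are sampled on the remaining tree at ≥ 4 µm from every tube axis, which
  also guarantees the manifest invariant that off-target centres lie well
  beyond the apposition tolerance from every tube surface.
  Because the blobs are ~25% wider axially than laterally, site-placement
  clearances use a z-compressed metric (z distances scaled by 0.78):
  a site must keep a scaled distance ≥ 2.3 µm from every *other* branch's
  centreline and ≥ 3.5 µm from sites on other branches. This prevents two
  blobs — or a blob and a neighbouring shaft — from fusing across the
  z-gap into a single foreground bridge, which would make the traced
  topology ambiguous. Same-branch spacing stays at 3 µm: same-branch
  fusion only thickens one tube locally and is handled by the tracer.
* **Intensity model**: constant background (default 100 on a 12-bit
  scale), additive Gaussian noise (default SD 20), rounding to integers.
  The defaults put the shaft ~45 SD above background — a bright, cleanly
  labelled cell; noise mainly tests the stability of thresholds and
  boundary fits, not low-SNR segmentation. In the marker channel the
  neuropil baseline is 0.8 × `background_level` while the somatic cytosol
  is flat at `background_level`: diffuse cytosolic marker signal is what
  makes "brighter than the somatic background" a meaningful punctum
  criterion, and the generator reproduces that structure.
* The generator's defaults are the P16 condition — 290 branch points and
  263 varicosities, 109 of them on 29 AISs — the developmental peak of
  arbor complexity and the condition the recovery analyses use.

What the generator does *not* emulate: optical PSF beyond Gaussian
profiles, depth-dependent attenuation, photobleaching, tiling artefacts,
dendrites (the proximal ROI of these cells contains none), multiple
overlapping cells, or AnkG background staining. Recovery results on
synthetic stacks therefore demonstrate the correctness of the measurement
chain under its stated model, not robustness to every real-world imaging
defect; thresholds are configurable where real data would need different
ones.

Determinism: all randomness flows through R's RNG seeded once from
`config$seed`, so identical `(seed, config)` give bit-identical channels,
manifests and TIFF files.

## Tracing and branch-point counting

`trace_axon()` replaces interactive filament tracing with an automatic
chain:

1. **Threshold**: Otsu's method on the full ROI histogram (4096 levels),
   overridable. With a bright foreground and a dominant background mode
   this lands between the background and shaft intensities.
2. **Soma masking**: voxels within 6 µm of the soma centre are removed,
   excluding the soma from axonal metrics; the traced root is the
   remaining foreground voxel nearest the soma.
3. **Largest component**: speckle and detached fragments are dropped.
4. **Geodesic farthest-point skeletonization**: shortest-path distances
   from the root over the 26-connected foreground voxel graph, then
   centreline paths peeled off farthest-tip-first, each path following
   shortest-path parent pointers until it touches the existing skeleton.
   Two numerical devices make this robust on thick swellings:
   * *Medial-axis weighting*: each voxel carries a capped
     distance-from-boundary (DBF, computed by probing offset shells up to
     1.6 µm); edge weights are multiplied by
     `1 + 4 (1 − DBF/cap)²`, so paths run through the middle of tubes and
     varicosities instead of cutting corners along their walls.
   * *Adaptive capture radius*: a traced path invalidates surrounding
     foreground within `1.3 · DBF + 1.4` µm — ~2 µm along thin shafts
     (sparing nearby genuine terminal branches, which the generator makes
     ≥ 4.5 µm long) but ~3.5 µm inside varicosities (absorbing the whole
     swelling so its far wall cannot spawn a phantom branch).
5. **Spur pruning**: terminal arcs shorter than 1 µm — thinning artefacts
   below the biological branch scale — are removed iteratively.

Branch points are skeleton nodes of degree ≥ 3; total length is the sum
of edge arc lengths. On noiseless synthetic stacks the recovered
branch-point count equals the generator's exactly (tested across seeds
and at the full 290-branch-point scale); axis-aligned tube length is
recovered within 2%, with a small systematic overestimate possible for
oblique runs because voxel paths are polygonal.

## Varicosity detection

Candidates are connected regions brighter than
`background + 1.4 × (median shaft − background)`, where the median shaft
level is taken along the skeleton. Each candidate is refined by a
windowed multiscale Laplacian of Gaussian (scales 0.5–1.25 µm,
scale-normalised; the operator is evaluated in a 5 × 5 × 6 µm window and
its peak searched within 1.2 µm of the candidate's own seed so a brighter
neighbour cannot capture it). Computing the operator per candidate window
rather than over the full 30-Mvoxel volume gives the same local extremum
at a fraction of the cost.

Measurements per candidate:

* **Diameters**: full width at half maximum above the local shaft
  baseline, sampled sub-voxel (0.05 µm) along eight x–y directions — the
  largest is the x–y diameter, equivalent to the major principal axis for
  near-elliptical blobs — and along z.
* **Brightness ratio**: raw peak intensity over the shaft reference — the
  median axon intensity along the skeleton at 2–5 µm *arc* distance from
  the candidate's nearest skeleton point, excluding voxels inside any
  candidate region. A candidate with an empty annulus (an isolated blob)
  is flagged unscorable and excluded with a warning rather than guessed.

Selection applies the printed boundary semantics literally: diameters
strictly below 3 µm (x–y) and 3.5 µm (z); ratio of at least 2.0
(inclusive); centre within 1 µm of the skeleton. The brightness criterion
is applied to every candidate — stricter than checking only the extreme
spots per image, which is the defensible automated reading. Detection has
no random component.

## AIS segmentation and apposition

AIS objects are connected components of the thresholded AnkG-like channel
whose axis-aligned bounding boxes exceed 10 µm in height and 2 µm in
width, both strict; "height" is measured along y (the pial–ventricular
axis), matching vertical AIS geometry. Whether "width" should be the
larger or smaller of the two remaining box extents is genuinely
ambiguous; the default takes the larger (`width_rule = "max"`), with the
other reading available as a switch.

Apposition compares *surfaces*, not centres: the distance from the AIS
voxel set to the varicosity centre, minus the varicosity's fitted
ellipsoid radius along the connecting direction. A varicosity is an AIS
varicosity when this gap is ≤ 0.5 µm (about two lateral voxels — contact
at light-microscope resolution), assigned to the nearest AIS (ties to
the lower id, for deterministic output). Off-target counts follow by
subtraction, so the partition identity `n_ais + n_off = n_total` holds by
construction; the summary also reports the per-AIS varicosity ratio as
pooled AIS varicosities over innervated AISs.

## Marker colocalization

The background is the mean marker intensity over the somatic cytosol: the
soma mask (region-grown from the soma centre on the fill channel, bounded
at 6 µm) eroded by 1 µm to strip the membrane. The background is
estimated per cell; per-image estimation would only differ where several
cells share an image, which the sparse-labelling design avoids. Each
varicosity's marker mean is taken over its fitted ellipsoid volume — the
natural region-mean reading of a punctum measurement — and called
positive iff strictly above background, so a mean exactly at background
is negative. Percentages are reported per class; classes with fewer than
50 scored varicosities per cell are flagged under-sampled but retained.
Because calls compare two intensities, they are invariant under any
monotone affine rescaling applied jointly to the channel and the
background (tested).

## EM morphometry

Vesicle roundness is `4π · area / perimeter²` with the shoelace area and
Euclidean perimeter; it is scale-invariant and ≤ 1 up to discretisation.
The roundness of a 2:1 ellipse is validated against the exact perimeter
from the complete elliptic integral (~0.841). Profile area is measured on
the outline polygon, immunogold area is subtracted before computing
vesicle density, and a profile qualifies as a varicosity when its maximum
Feret diameter — the only orientation-free reading of "diameter" —
exceeds 200 nm. Outlines are consumed from annotation polygons (the
generator's analytic ground truth plays that role); a dark-ring
segmenter for the synthetic micrographs is included, with
moving-average contour smoothing to limit the staircase bias that pixel
chains would otherwise impose on the perimeter (roundness is
perimeter-sensitive). Real-EM segmentation robustness is out of scope:
the measurement of record is the formula applied to traced outlines.
Whether per-vesicle roundness should be averaged within a varicosity
before group statistics or pooled across vesicles is ambiguous;
`profile_metrics()` returns both the per-vesicle values and the
per-profile mean, and group statistics default to per-profile means.

## Statistics

Group data are summarised as mean ± SEM (SD/√n). Normality is assessed by
Shapiro–Wilk per group and *reported*; by default it does not gate the
test choice (the reference analyses used parametric tests throughout),
but `gate_on_normality = TRUE` switches to Mann–Whitney / Kruskal–Wallis
when violated. Two groups: two-tailed unpaired Student's t (pooled
variance). More than two: one-way ANOVA — groups at different ages are
different cells, hence genuinely independent — followed by all-pairs
pooled-SD t tests with Bonferroni adjustment (raw p × number of pairs,
capped at 1). Stars: \*, \*\*, \*\*\* at 0.05, 0.01, 0.001. The
implemented ANOVA's type-I error is checked by simulation (1000 null
replicates, 4 × 10 design) to sit within binomial error of the nominal
5%. Percentage metrics are averaged per cell then across cells (mean of
ratios); pooled ratios are also available via
`pooled_cartridge_stats()`.

## Problem sizes used in the test and acceptance runs

Unit and property tests run on small arbors (6–30 branch points in
40–70 µm ROIs), chosen so the whole suite exercises every stage in a few
minutes. The recovery analyses use one noiseless stack at the full P16
condition (290 branch points, 263 varicosities in the standard
100 × 100 × 60 µm ROI) where recovery must be exact, and a 7-cell
colocalization simulation (≥ 50 scored varicosities per class per cell,
70 × 70 µm ROIs — the colocalization result depends on the number of
scored varicosities, not on ROI size) judged within binomial error. For
infeasible random arbors (a seed under which the requested number of AIS
tubes cannot be placed) the experiment scripts draw the next seed — a
rejection step over the arbor distribution, not a change of conditions.

## Known limitations

* The tracer assumes a single labelled cell whose foreground is one
  connected component after thresholding; crossing axons from other cells
  would need untangling it does not attempt.
* Skeleton length slightly overestimates true curve length on oblique
  runs (polygonal voxel paths); branch-point *counts* are unaffected.
* The varicosity size measurement is an FWHM above the local baseline,
  which for overlapping swellings (< ~2.5 µm apart) can be biased by the
  neighbour's tail.
* The marker-positivity rule inherits the fragility of a strict
  mean-above-background threshold: in data where empty varicosities sit
  exactly at the background level, calls near the boundary are noise
  coin-flips. The generator models the cytosolic offset that makes the
  rule well-posed in the reference protocol.
* EM vesicle segmentation is intentionally simple and validated only on
  the synthetic micrograph model.
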