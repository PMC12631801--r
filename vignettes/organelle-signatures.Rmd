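---
title: "Organelle signatures: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle signatures: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orgsig` measures the organelle landscape of single cells from 3D
multi-channel label images and screens the resulting per-cell metric
vectors between experimental groups. This vignette is the package's own
account of the underlying models, the conventions that had to be fixed
where several reasonable definitions exist, and the limits of what the
synthetic test bed can show.

## The measurement frame

A cell image is a set of co-registered 3D voxel grids in axis order
(Z, Y, X) with anisotropic physical spacing (sz, sy, sx) in micrometres:
a cell mask and nucleus mask (each treated as exactly one object), six
organelle channels (ER, GL, LD, LS, MT, PO) as binary masks or instance
labels, and optional intensity channels. One cell per image is assumed —
the analysis is explicitly per-cell, and multi-cell fields of view must be
cropped upstream. Physical coordinates are voxel index × spacing, and all
reported quantities are in real-world units (μm, μm², μm³).

## Instancing

Two foreground voxels belong to the same object iff they are
26-adjacent (face, edge or corner contact). The biological reading is
deliberate: structures that come within one voxel's distance of each other
cannot be resolved as separate at this sampling, so they are measured as
one object; no watershed splitting is attempted. Labels are assigned in
raster order of each component's first voxel (Z slowest, X fastest), which
makes labeling deterministic and lets tests compare against an independent
graph-components oracle. The ER, cell and nucleus channels are collapsed
to a single object a priori; disconnected ER fragments therefore count as
one object of combined volume, and the ER object count is constant 1.

## Morphology conventions

Most object metrics are standard, but three needed a fixed convention:

* **Surface area** is a triangulated isosurface: the binary object is
  padded by one background voxel, smoothed with a separable Gaussian of
  σ = 0.85 voxel per axis, and the 0.5-isosurface is extracted by marching
  tetrahedra with linear edge interpolation in physical coordinates.
  On the binary volume directly, an isosurface overestimates the area of a
  digitized r = 10 voxel sphere by ~28% (voxel-face counting by ~50%); with
  the pre-smoothing the same sphere is recovered to within ~1%, and σ was
  fixed at 0.85 voxel from that calibration. Objects only a few voxels
  across are underestimated by this estimator (the smoothing kernel is
  comparable to the object), a resolution limit shared by any
  surface estimate at this sampling; if smoothing erases an object
  entirely, the unsmoothed surface is used so areas are never zero for
  non-empty objects.
* **Euler number** is the characteristic of the cubical complex of the
  union of closed voxel cubes (V − E + F − C), i.e. the 26-connectivity
  foreground convention, consistent with the instancing topology. It
  counts components − tunnels + enclosed cavities; a hollow shell scores 2,
  and a densely anastomosed tube network scores strongly negative.
* **Solidity** is foreground voxel count divided by convex-image voxel
  count (voxel centers inside the 3D convex hull of the object's voxel
  centers). This ratio is scale-free — anisotropy cancels — and gives
  exactly 1 for convex digitized solids, including a single voxel, keeping
  the invariant solidity ≤ 1. A definition based on the physical volume of
  the point-center hull was rejected because it exceeds 1 for any
  digitized convex body (the hull of an n³ cube's centers has volume
  (n−1)³). Degenerate objects are handled by rank: collinear sets are
  their own convex image; planar sets use a 2D hull in their plane.

Major axis length is the moments-based ellipsoid axis
4·sqrt(λ_max) of the voxel-center covariance matrix computed in physical
coordinates, so spacing enters before the eigendecomposition. Extent is
voxel count over bounding-box voxel count (identical to the physical
ratio). SD of object volumes uses the sample (n − 1) denominator and is
reported missing for n < 2; medians of even-length sets average the two
central values.

## Interaction sites

An interaction site for a pair of organelles is a 26-connected region of
the voxelwise intersection of the two semantic foregrounds; the overlap is
computed before re-instancing so that site topology does not depend on
instance boundaries, and each site records the parent instances it touches
on both sides (a site spanning two touching parents stays one site with
two parents). Sites are measured with the same morphology suite, and the
percentage of parent objects involved is reported per side. At confocal
sampling a voxel overlap is a proxy for both membrane contact and close
proximity; no distance-resolved classification is attempted. The 15 pairs
are always reported in the fixed lexicographic order ER-GL … MT-PO.

## Distribution profiling

The XY geometry follows proportional-ring designs: on the cell footprint
(any-voxel projection), every pixel gets the normalized radial coordinate
d = D_nuc/(D_nuc + D_edge), with both Euclidean distance maps offset by
one pixel so that d = 0 exactly at the nucleus border and d = 1 exactly at
the cell border. Nucleus-footprint pixels are ring 1 (ring 1 thus contains
the nucleus and the volume above and below it); other pixels are binned
into five equal d-intervals. Eight 45° wedges start at the +x axis from
the nucleus centroid; wedge statistics are therefore orientation-dependent
at the margins, which is irrelevant for the rotation-invariant mode/SD
summaries and averages out in the wedge CV median. Z bins split the plane
range containing cell mask into ten contiguous bins, sizes differing by at
most one plane, remainder planes assigned to the bottom bins; with fewer
planes than bins the excess bins are empty with zero cell volume.

Raw regional volume is normalized as
n(r) = (raw(r)/total) / (regional cell volume(r)/cell volume): density
enrichment relative to uniform occupancy, with the testable identity
n ≡ 1 for an object equal to the cell mask. The summary statistics are the
mode (argmax of n, ties to the innermost region) and the **positional**
SD — the volume-weighted standard deviation of the region index with
weights n(r)/Σn(r) — chosen over the SD of the n values because the mode
is an index and both statistics then live on the same axis. The wedge CV
is the sample SD over mean of the eight normalized wedge volumes, as a
ratio (not percent); rings with zero object volume are excluded from the
per-cell median, and wedges with zero cell volume are excluded from a
ring's CV.

## The curated signature

The full per-cell panel carries every computed summary (including cell and
nucleus morphology, intensity statistics when intensity channels exist,
percent-involved metrics, and the per-region normalized volumes). The
curated signature is the fixed 234-column subset used for screening:

* morphology, 65 = 6 organelles × 11 (volume fraction, total volume,
  count, median object volume, SD of volumes, and medians of SA:vol,
  equivalent diameter, extent, Euler number, solidity, major axis length)
  minus the constant ER count;
* interactions, 60 = 15 pairs × (site count, total, median, SD of site
  volumes);
* distribution, 109 = 21 objects (6 organelles + 15 pairs) × (XY mode,
  XY SD, XY median CV, Z mode, Z SD) + 4 nucleus metrics (no wedge CV for
  the nucleus).

Cells lacking an organelle get count/total volume 0 and missing medians —
missingness is informative and is never imputed; no outlier removal is
performed anywhere.

## The statistical screen

Group comparisons use two-sided Mann-Whitney U tests per metric with
pairwise deletion of missing values; a metric is excluded when either
group retains one or fewer values. The exact U distribution is used when
both groups have at most 8 observations and no ties; otherwise the normal
approximation with tie correction (the behaviour of standard statistical
software at these group sizes). Multiplicity is controlled by the
two-stage Benjamini-Krieger-Yekutieli linear step-up procedure at FDR
q = 0.10: stage 1 is a BH step-up at q' = q/(1+q); with r₁ rejections
(0 < r₁ < m) stage 2 re-runs the step-up at q'·m/(m−r₁). Reported
q-values invert the stage-2 threshold with r₁ held at its stage-1 value,
so q_value ≤ q exactly reproduces the rejection set; significance tiers
are q ≤ 0.1/0.05/0.01/0.001. Mean rank difference (group A mean rank −
group B mean rank under joint ranking) is the effect-size axis; log2 fold
changes are ratios of group means, defined only when both means are
strictly positive — means rather than medians, since median-based ratios
degenerate for the many zero-inflated count metrics.

PCA standardizes each metric to zero mean and unit SD after dropping
zero-variance columns and columns with missing values (PCA needs a
complete matrix; metrics undefined for absent phenotypes carry their
information in the screen instead). Component retention uses parallel
analysis: eigenvalues are compared rank-by-rank with the 95th percentile
of eigenvalues from 1000 standard-normal matrices of the same shape
(standardized identically), and the leading run of components above their
percentile is retained. The i.i.d. normal null is the conventional choice
for z-scored data. Hierarchical clustering uses Ward ("ward.D") linkage
on Euclidean distances of the same standardized matrix.

## Track dynamics

Tracks are 2D point series at a fixed frame interval (default 5 s).
Displacement is first-to-last straight-line distance; total distance the
summed step lengths; speeds are step length over interval. Rolling
statistics use all 10-frame windows at stride 1; each window contributes
its median speed, SD of speeds, and tortuosity (window path length over
window net displacement, ≥ 1, missing when the window returns exactly to
its start), and windows are aggregated by the median — a robust choice
fixed here because cross-window aggregation is not standardized across
tracking tools. Tracks shorter than the window fall back to one
whole-track window and are flagged.

## The synthetic test bed

The phantom generator exists so that every pipeline stage has computable
ground truth. A cell is a smoothed random-blob footprint (low-order
harmonic perturbations of a disc) extruded with a dome height profile over
a flat base — an adherent cultured cell — with an interior ellipsoidal
nucleus; the default grid is 24×96×96 voxels at (0.41, 0.16, 0.16) μm,
i.e. a ~15 μm cell with axial sampling typical of high-NA confocal stacks
and lateral sampling at half of a typical acquisition, chosen to keep a
full two-group simulation in the tens of seconds. Organelles are spheres
(LS, PO, LD), capsule rods (MT, GL) or a connected random-walk tube
network dilated to tubes (ER — which exercises the tunnel-counting Euler
metrics), placed by rejection sampling with per-organelle Beta-distributed
radial (perinuclear↔peripheral) and Z biases, kept inside the cell and
out of the nucleus. With clustering rate 0, objects of a channel are kept
more than one voxel apart, so ground-truth counts provably equal instance
counts; planted pairwise overlap rates place a fraction of one channel's
objects to interpenetrate a partner channel's objects by a set depth.
Placement is capped at 1000 attempts per object (explicit
infeasible-placement error); forced or clustered placements that cannot
find room fall back to unbiased placement for the second half of the
attempts, and only successful forced placements are recorded as planted.

Two presets encode the contrasts the pipeline is designed to detect:
`neuron_like` (more and longer-lived mitochondrial rods: count 50–70,
denser ER network, MT-on-ER overlap rate 0.55) versus `astrocyte_like`
(more and larger lysosomes: count 30–42, radius 0.38 ± 0.13 μm, strongly
perinuclear Beta(0.8, 6) radial bias, PO-on-LS overlap rate 0.60, fewer
mitochondria). Lipid-droplet counts are drawn around means of ~12.3 and
~18.5 per cell respectively. These parameters were fixed once, as
realistic magnitudes for cultured neural cells, and are the study
conditions of the test suite.

What the phantoms do **not** emulate: fluorescence intensity, the point
spread function, spectral mixing, segmentation errors, or the texture of
real organelle networks. Passing tests therefore demonstrate that the
measurement and screening algorithms are correct on known geometry — not
that any particular segmentation of real microscopy is accurate.

## Problem sizes used by the tests

The oracle suites run ~100 random masks up to 16³ voxels against
graph-components, cubical-complex, bounding-box and independent
convex-hull implementations; analytic limits use a digitized r = 10 voxel
sphere. FDR calibration simulates 500 replicates of 200 uniform p-values;
parallel-analysis calibration runs 100 seeded noise-only analyses of
20 × 10 matrices with 200 simulations each. The end-to-end recovery study
simulates 20 + 20 phantoms (seeds 1–40) at the default grid, screens the
curated signature, and checks that every planted contrast is flagged at
q ≤ 0.1, that metrics generated identically in both groups stay within
the FDR budget among flagged metrics, and that PC1 score ranges of the two
groups do not overlap. These sizes are the package's own trade-off between
statistical resolution and a test suite that completes in a few minutes.

## Known limitations

* One cell per image; no multi-cell fields or cell tracking.
* Isotropic XY spacing is required by the ring geometry.
* Interaction sites are voxel overlaps; no distance-band analysis below
  voxel resolution.
* The full (non-curated) panel is documented by construction (~600
  columns) rather than matching any external enumeration verbatim.
* Surface areas of objects a few voxels across are systematically
  underestimated; comparisons between groups measured at the same
  resolution remain valid.
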