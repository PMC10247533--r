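---
title: "Surface extraction and rosette morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface extraction and rosette morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During gastrulation, mouse axial mesoderm cells undergo a
mesenchymal–epithelial transition below the distally convex surface of the
egg cylinder: they assemble into multicellular rosettes — groups of five or
more cells elongated toward a shared, membrane-rich central domain — that
acquire junctional (ZO-1) and apical (aPKC, Pals1) polarity, often develop
a central lumen, and radially intercalate into the squamous surface
endoderm to build the node and notochordal plate. Quantifying this process
from 3D confocal z-stacks requires separating signal *on* the curved
embryo surface from signal *below* it, measuring the emerged epithelium,
classifying rosettes by their position, maturation stage and lumen
geometry, and following junctional regions through time-lapse movies.

`embryomorph` implements that analysis chain as composable, calibrated
operations, together with a synthetic embryo-stack generator that renders
every structure the analysis must detect — with complete ground truth — so
that the whole pipeline can be validated end to end.

# Surface extraction

The embryo exterior is annotated as sparse per-slice outline polygons (in
practice hand-drawn every 2–5 slices near the curved surface and much more
sparsely in deep, low-curvature regions). `interpolate_contours()` fills
the gaps by linear interpolation of per-slice signed distance fields. Two
implementation choices matter:

* the signed distance is computed against the **polygon geometry** (exact
  point-to-segment distances at pixel centres), not against a rasterized
  mask; boundary interpolation is then sub-pixel accurate, and blending
  two circles yields a circle of linearly interpolated radius.
* a slice annotated as **empty** next to a non-empty one is treated as the
  neighbouring outline collapsed onto its innermost point (a cone
  collapse), not as an arbitrary far-away level set. This is how the
  embryo apex vanishes between two annotation planes.

Linear distance-field interpolation reproduces the behaviour of
ROI-interpolation tools on convex outlines; its known bias is that a
spherical surface grows as the square root of depth while the
interpolation is linear in depth, so widely spaced annotations slightly
under-estimate mid-slice sections. At a 4-slice (8 µm) stride on the
default synthetic embryo the reconstruction still reaches a voxel IoU of
about 0.98 against the true interior.

The filled interior is eroded by a physical depth (`erode_physical()`,
default 10 µm — the midpoint of the 9–12 µm range used in practice) using
a true 3D anisotropic Euclidean distance transform (separable
lower-envelope algorithm, implemented in C++ since no installed R package
provides a 3D anisotropic EDT); a 2D per-slice mode is available. Voxels
beyond the stack border are not treated as background, so the mask is not
eroded from the image edges.

The eroded interior indicator is Gaussian-blurred (σ in µm,
anisotropy-aware; default 2 µm, about one membrane-transition width — the
blur radius is not specified by the original procedure and is exposed as a
parameter) into a weight field $w \in [0,1]$, and the stack is split:

* **soft mode** (default): surface $= I(1-w)$, subsurface $= I\,w$. This
  conserves signal exactly, voxel by voxel.
* **fiji_subtract mode**: surface $= \max(0, I-w)$, subsurface
  $= \max(0, I-(1-w))$, replicating the clamped 8-bit image-calculator
  arithmetic of the published figures in fractional units. With σ = 0
  every non-zero voxel lands in exactly one output.

Maximum-intensity projections of the two halves give the emerged and
unemerged views; `slab_projections()` produces sequential projections in
half-open depth bins *below the extracted surface* (per-column height
map), e.g. ten 5-µm slabs over the distal 50 µm, because the analysis
depth tracks the curved surface rather than absolute z. `reslice()`
produces transverse/sagittal views with output slice spacing equal to the
original z step and nearest-neighbour resampling.

# Morphometrics

`segment_epithelial_regions()` binarizes the junctional projections,
closes sub-µm gaps, labels 8-connected lattices and fills their enclosed
apices (4-connected background, so a diagonal web still seals its holes).
Regions from the surface projection are *emerged*, from the subsurface
projection *unemerged*; the emerged fraction is emerged / (emerged +
unemerged) area. The manual criterion "axial mesoderm cells have smaller
apical surfaces than the endoderm" is operationalized as a median
enclosed-apex-area threshold (default 50 µm², configurable — no numeric
cutoff exists in the literature); "highly constricted cells along the
cluster perimeter" are excluded from cell counts via a minimum counted
apex area (default 2 µm²). Mean cell area is cluster area divided by the
cell count, with an explicit `NA` when the count is zero. External
(manual) cell counts can be supplied to `summarize_clusters()`.

# Rosette analysis

Rosette centres are inputs (ground truth or annotation), mirroring manual
identification by junctional/actin enrichment. Location classes are
evaluated in precedence order:

1. **partially emerged** — the central domain is open to the external
   embryo surface: a connected path of signal-free voxels, not crossing
   any cell-occupied voxel, links the central domain to the exterior.
   The test runs inside a local cylinder (default radius 10 µm) about the
   rosette axis so that unrelated surface gaps elsewhere cannot
   contribute.
2. **endoderm-contacting** — "visibly contacted" is operationalized as
   26-connected voxel adjacency between the central domain and the
   endoderm mask.
3. **basal** otherwise; one axial mesoderm cell diameter (default 10 µm,
   a free parameter — absolute mesoderm cell diameters are not published)
   is the distance scale of the rule.

This precedence implements the closest-region rule for composite
morphologies.

A **lumen** is "clear negative space": a dark connected component
(default threshold background + 2 noise sd) enclosed by apical-marker
signal, not background-connected (components touching the analysis patch
border are treated as exterior-connected), of at least 5 µm³. The default
is full 3D enclosure; a `"2d"` mode checks enclosure in at least one
transverse plane instead, matching the looser manual criterion. Volume is
voxel count × voxel volume; the transverse area is the largest xz
cross-section; a lumen is *elongated* (tunnel-like) when the ratio of its
longest to shortest principal extents exceeds 2. Because optical sections
are 2 µm apart, lumens with radii below about 1.5 voxels are not
resolvable and are reported as absent.

**Staging** follows the junctional morphology: a compact punctum below a
1.5 µm Feret diameter is a *spot*; a linear domain not at a multi-cell
vertex is an *edge*; uninterrupted central signal at a vertex of five or
more cells is an *early rosette*; a fragmented or holed (webbed,
latticed, reticular) central pattern is a *late rosette*. The geometric
thresholds are operationalizations and are configurable.

**Granules** (1–2 µm apical-protein puncta, about one per cell) are
detected with a matched filter: in-plane Gaussian smoothing at 0.5 µm, a
threshold of 8 robust standard deviations (MAD) above the median — a
scale-free criterion that adapts to the noise floor — and an analytic
inversion of the thresholded blob radius for the diameter estimate, with
the filter width removed in quadrature. Sizing uses in-plane extent only:
at 2 µm optical sectioning the axial extent of a 1–2 µm granule is not
resolvable, and the 1–2 µm band is applied with ±0.3 µm slack for pixel
rasterization. Marker distributions per region use the five-category
vocabulary `none` / `granular` / `transitional` / `apical` /
`junctional`.

# Time-lapse tracking

Movies are analysed on projections (as in practice; tracking is not
volumetric). Each frame is thresholded and labelled; the label image
carries the *filled* region (web plus enclosed apices), which makes
overlap linking robust to motion where thin junctional webs would barely
overlap themselves. `build_tracks()` links greedily by IoU (default
minimum 0.25) with 1-frame gap closing; a successor with two or more
predecessors is a merge node. The predecessor with the largest overlap
continues its track (tie: lowest id); the others terminate at the merge.

The event taxonomy: *pre-clusters* are solid junctional domains,
*clusters* enclose at least one apex-sized hole (default 4 µm²). Every
track that begins as a pre-cluster receives exactly one outcome —
expansion at its first pre-cluster→cluster transition, disassembly if it
ends before the final frame other than by merging, persistence otherwise.
A pre-cluster consumed by a merge counts as persistence: it neither
expanded nor disappeared. One coalescence event is scored per merge node
(a k-way merge counts once), with the participants' states at the frame
before the merge. In synthetic movies regions cannot leave the field; for
real data a border-touch flag suppresses disassembly calls at the image
boundary.

Emergence is an endpoint rule on the emerged fraction (intensity share of
a region's projected signal in the surface projection) at first detection
and at the end of the 7-hour window (35 frames at the 12-min acquisition
interval): emerged at both endpoints = remains emerged; below at both =
does not emerge; below→emerged = emerges. Partially emerged endpoints
score *emerges* only with increasing emergence; stable partial emergence
counts as remains emerged; and regression — including the time reversal
of an emergence event — scores does not emerge. This deliberate asymmetry
follows the scoring convention of the live-imaging analysis.

# The synthetic embryo

The generator renders a five-channel stack (membrane, junction, nuclei,
apical marker, granules) over a spherical-cap height map (radius 150 µm —
shallow curvature typical of the distal egg cylinder; z index 1 is the
distal-most slice, as acquired with the embryo mounted distal side down).
Default calibration is 2 µm z steps and 0.5 µm pixels (20× acquisition);
the default field is 144 × 96 µm. The endoderm is a 6-µm squamous shell
carrying a jittered-grid centroidal tessellation (15 µm cells, dim
junctional lattice); emerged mesoderm clusters (default 7 per embryo, the
order observed at late-streak stages) are 24-µm patches of 5-µm apices
with bright junctions. Subsurface rosettes (default 8 per embryo) are
oblate (lateral radius = one mesoderm cell diameter, axial radius half
that — keeping cell bodies within the imaging depth under the curved
surface), with early (solid junctional focus) or late (equatorial ring
plus spokes around an apical shell) morphology; half develop lumens,
a quarter of which are tunnels elongated along the anterior–posterior (y)
axis, rendered as capsules whose analytic volume is
$\pi r^2 L + \tfrac{4}{3}\pi r^3$. The apical shell thickness always
exceeds the z step so that lumens remain sealed in 3D after voxelization.
Endoderm contact is modelled as a basally displaced endoderm cell process
reaching down to the rosette's central domain — matching the observed
deformation of surface cells toward approaching rosettes — so that
default rosette bodies stay below the erosion transition; partially
emerged rosettes (planted on request) carve a cup open to the exterior
through the shell. Granule centres are z-snapped to voxel centres and
kept 5.5 µm apart (about one per 10-µm cell, so nearest neighbours at
cell-scale spacing); intensities are fractional in [0, 1] with additive
Gaussian noise plus an intensity-scaled component.

Randomness is organised in documented sub-streams (`seed + 0` … `seed + 6`
for layout, rosette placement, lumen draws, stages, granules, noise and
the movie schedule), so any draw sequence can be replayed independently —
the lumen-presence Bernoullis, for instance, are the first
`n_rosettes` uniforms of stream `seed + 2`, with a fixed draw count
regardless of outcome.

Movies render a single junctional channel over a static endoderm lattice:
scheduled regions persist, expand (solid disk → ring-and-spokes),
disassemble, approach and coalesce (partners close along their joining
axis, remaining distinct one frame before the merge and overlapping at
it), and translocate surfaceward to emerge. The schedule is the ground
truth for the event taxonomy; merged tracks follow the same
largest-partner continuation convention as the tracker.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: optical point-spread blur and
spectral bleed-through, photobleaching and drift, embryo growth and
deformation during imaging, irregular cell shapes and intensity
heterogeneity within a class, touching or interleaved rosettes, and
annotator disagreement beyond Gaussian vertex jitter. Validation on this
generator demonstrates the correctness of the measurement chain, not the
difficulty of segmenting real embryos.

# Numerical choices and degenerate inputs

* Distances are physical (µm) with anisotropic voxel scaling throughout;
  coordinates are 0-based with voxel centres at integer multiples of the
  voxel size; depth bins are half-open.
* Self-intersecting contour polygons are rejected with their slice
  index; empty junctional patches are an error for staging, while
  sub-minimum tracking patches are ignored rather than errors.
* Mean cell area with a zero cell count is an explicit `NA`, never a
  division.
* The per-test problem sizes (default embryo 32 × 288 × 192 voxels;
  movies 36 frames at 24 × 128 × 128) were chosen so the full validation
  suite exercises every module at realistic scale on a single CPU.

# Known limitations

* Linear distance-field interpolation under-estimates sphere-like
  sections between widely spaced annotations (see above).
* Granule sizing is in-plane only; axial diameters are not estimated.
* Rosette centres are inputs; automatic rosette detection is out of
  scope, as is any between-genotype statistics.
* Tracking operates on projections; regions that overlap in projection
  but are separated in depth would be merged, as in the manual analysis.
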