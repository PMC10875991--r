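---
title: "Deriving cerebral angiograms, centerlines and straightened vessels from CT perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving cerebral angiograms, centerlines and straightened vessels from CT perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A CT-perfusion (CTP) study acquires the same head volume repeatedly while a
contrast bolus passes through the circulation, so every voxel carries a
time-attenuation curve (TAC): Hounsfield units as a function of acquisition
time. Conventional clinical arteriograms (CTA) and venograms (CTV) are
single-phase acquisitions timed to arterial or venous enhancement; they often
truncate the venous system and mix arterial and venous voxels. Because the
full bolus passage is present in CTP data, both systems can instead be
*derived* from it: vessels are the voxels whose TACs change strongly, and
arteries are distinguished from veins by *when* each voxel's TAC peaks.

`ctpangio` implements that derivation end to end, plus the two
geometry stages that make a single vessel-of-interest reviewable: centerline
extraction between two seed points and straightening (curved planar
reformation) of the vessel around that centerline. Every stage is validated
on synthetic vascular phantoms with analytic ground truth; no patient data
is required anywhere.

# Pipeline stages and their assumptions

## Skull stripping

Bone is by far the brightest tissue in a non-contrast frame, so a plain
threshold on the first frame (acquired before contrast arrival) at
**155 HU** marks the skull. Everything outside the largest enclosed cavity
of the non-skull region — scalp, face, air — is extracranial and removed
together with the skull; removed voxels are set to the air sentinel
(−1024 HU) in every frame so the brain voxel set is identical across time.
The stage assumes the frames are already rigidly registered (phantoms are
born registered; for patient data any registration tool can be applied
upstream) and that the skull forms a closed shell in the field of view —
when it does not, the largest non-skull component is kept instead.

## Vessel segmentation (FG map)

Each voxel's TAC is convolved with a digitized first-order
derivative-of-Gaussian kernel (σ = 3 in frame-index units, 1 × 5 taps,
analytic values `-(x/σ²)·exp(-x²/2σ²)` at integer offsets). The taps are
odd-antisymmetric and sum to zero, so any constant (non-enhancing) TAC maps
to exactly zero, and the response is positive on contrast uptake. The
summed absolute response

FG = Σᵢ |v′ᵢ|

is large precisely for voxels with strong bolus dynamics — vessels — and
scales linearly with enhancement amplitude. Thresholding FG yields the
vessel mask. No threshold value is prescribed by the method itself, so the
default is Otsu's threshold on the `log(FG+1)` histogram of positive-FG
voxels: parameter-free, reproducible, and recorded in the run manifest;
an explicit value can be supplied instead. Convolution uses edge
replication at the series boundaries, which avoids spurious derivative
spikes on the first and last frames.

## Artery–vein separation (TTP valley)

Contrast reaches arteries before veins, so each vessel voxel's time-to-peak
(TTP) is computed from the *smoothed* derivative curve: with `t_(I+1)` the
first sample where the derivative is no longer positive and `t_I` the
sample before it, linear interpolation of the zero crossing gives

a = (v′₍I+1₎ − v′₍I₎)/(t₍I+1₎ − t₍I₎),  b = v′₍I+1₎ − a·t₍I+1₎,  t_ttp = −b/a.

Two robustness choices matter here. First, the crossing search is anchored
*after the maximum of the derivative*: with measurement noise the flat
pre-bolus baseline flips sign constantly, and the unanchored "first
crossing" rule would assign near-zero TTPs to a large fraction of venous
voxels; on noise-free curves the two rules coincide exactly. Second, a flat
crossing (a = 0) returns `t_(I+1)`, the analytic limit of the interpolation
as the slope vanishes. Voxels whose derivative never turns non-positive
(still filling when the scan ends) get `NaN` and are assigned to the veins,
the latest possible arrival.

The histogram of all defined TTPs is bimodal — an arterial mode and a
venous mode. The separation threshold `v_ttp` is the centre of the
minimum-count bin strictly between the two highest-prominence peaks
(prominence computed by the standard key-saddle construction). Binning
defaults to four bins per frame interval over the observed TTP range. Ties
in the valley break toward the lower TTP, a deterministic rule that favours
venous sensitivity; with well-separated modes the tied bins are empty and
the threshold lands at the lower edge of the empty gap, which is
immaterial for classification because no voxel lies there. A unimodal
histogram raises an error suggesting a manual threshold rather than
guessing.

## Centerline extraction

The centerline of the vessel-of-interest (a mask delineated upstream; the
phantom generators supply it) is defined between two user seeds. The
implementation follows the cross-section-centroid construction:

1. the mask's **wall** (outer contour) is the mask minus its 6-neighbourhood
   erosion;
2. a closed triangle **mesh** of the lumen surface is extracted as the
   0.5-isosurface of the lightly smoothed (σ = 1 voxel) binary mask by
   marching tetrahedra over the Kuhn 6-tetrahedra cube decomposition —
   crack-free by construction, with the smoothing converting the staircase
   voxel boundary into a sub-voxel-accurate surface (a rasterized ball's
   mesh area matches 4πr² to a few percent);
3. a slicing plane **marches** from the start seed: the normal starts along
   the seed chord and is re-estimated from the chord between consecutive
   accepted section centres, so sections stay near-orthogonal in curved
   vessels; every closed mesh–plane intersection contour contributes one
   node (side branches appear as separate contours and hence separate
   nodes);
4. **Dijkstra's algorithm** finds the minimum-total-Euclidean-length path
   from the snapped start node to the snapped end node; its node sequence
   is the centerline, with tangents by forward/central/backward differences
   and cumulative arc length attached.

Two refinements proved necessary for the section centres themselves. The
raw polygon centroid of a cross-section contour is correct for clean
sections but is dragged toward the opening where a side branch joins — by
the better part of a millimetre for branches 40–60 % of the parent calibre.
Since a centerline point is conceptually the centre of the largest inscribed
sphere, each node is instead placed by a robust circle fit to the contour
(trimmed algebraic Kasa fit refined with redescending Tukey weights); on
markedly non-circular contours the fit is repeated with the radius held
fixed at the running clean-section value, which locks onto the dominant
lumen arc and ignores the branch opening. On circular sections all these
estimators agree with the vertex mean to well under 0.1 mm.

Graph connectivity follows the "shortest distance among all centroids"
idea: nodes are connected to nodes up to six slices ahead, not only to the
adjacent slice. A node displaced by a junction lengthens any route through
it, so when a skip edge is available the path bypasses the distorted
section entirely; the corner cut by a skip edge on a curved vessel is
bounded by the chord sagitta, far below voxel size at millimetre steps and
clinically relevant curvatures. During marching, sections whose contour is
markedly non-circular (circularity 4πA/P² below 0.95) or far from the
predicted centre do not steer the heading — the plane coasts through on the
previous heading, with acceptance gates that widen with coasted distance so
the march re-locks cleanly. A second pass re-slices the mesh with planes
orthogonal to the first-pass path, which minimizes junction merging, and
re-runs the shortest path. Optional Laplacian smoothing (3-point moving
average, two passes, endpoints fixed) is available but off by default, so
reported deviations always refer to the raw path. Dijkstra itself is
deterministic (igraph, fixed node order), as is every other stage.

## Straightening (curved planar reformation)

A square sampling plane (side ≈ 4 lumen radii, default half-size 6 mm,
in-plane spacing 0.5 mm) is propagated along the centerline, which is first
resampled to uniform 0.5 mm arc-length steps because central-difference
tangents behave poorly on the uneven node spacing a shortest path produces.
For each step the angle between adjacent unit tangents, θ = arccos(nᵢ₋₁·nᵢ),
and the unit rotation axis perpendicular to both are formed, and every
sample of the previous plane (expressed relative to the previous centerline
point) is rotated by the closed-form Rodrigues formula

v′ = cos θ·v + (1 − cos θ)(u·v)u + sin θ(u × v)

and translated to the new point. The axis orientation is verified per step
— rotating nᵢ₋₁ must yield nᵢ, and the axis is flipped if not — because the
cross-product order and the unsigned angle leave the sign ambiguous.
Parallel tangents (θ = 0, axis undefined) degenerate to pure translation;
anti-parallel tangents are rejected as a nonphysical fold-back. This
sequential minimal rotation is the discrete rotation-minimizing frame: no
additional twist is introduced beyond what the geometry requires, every
plane remains an exact isometric copy of the template, and each plane's
normal equals its tangent.

The source volume (one frame, a temporal maximum-intensity projection, or
all frames) is then sampled by trilinear interpolation at every plane
coordinate; out-of-grid samples carry the −1024 HU sentinel. Stacking the
planes along a new z-axis renders the curved vessel as a straight tube.
The per-slice lumen area profile of a straightened binary mask
(`assess_caliber_profile()`) flags slices below 0.75× the median area as
stenotic and above 1.25× as dilated, and reports the extremal slices —
area scales with radius², so a 0.5× stenosis dips to a quarter of the
baseline area, far outside those bands.

# The phantom generators

Synthetic phantoms stand in for patient data, with three generators:

* **`phantom_scene()` / `rasterize_scene()`** — a miniature head: an
  ellipsoidal skull shell at 1000 HU (thickness 1.5 mm, comfortably above
  the 155 HU mask threshold), enhancing soft tissue filling the cavity, and
  arterial/venous tubes with gamma-variate bolus curves. The gamma-variate
  `A·((t−t₀)/(αβ))^α·e^(α−(t−t₀)/β)` is the standard analytic bolus model
  and has its peak exactly at t₀ + αβ, giving a closed-form ground-truth
  TTP. Defaults: artery t₀ = 4 s, α = 3, β = 2 (peak 10 s, 300 HU
  enhancement); vein t₀ = 8 s, α = 4, β = 3 (peak 20 s, 250 HU); soft
  tissue peak 30 HU; baseline 40 HU; 20 frames at 2 s; 0.5 mm isotropic
  voxels. With zero noise every voxel's TAC equals its label's model
  exactly, which is what makes exact-recovery tests possible.
* **`make_deviation_phantom()`** — a curved tube (arc radius 35–45 mm, span
  60–80°, lumen radius 3 mm) with 0, 3 or 6 side branches for the
  centerline validation. Branch geometry is not prescribed anywhere, so it
  was fixed once at values that genuinely perturb wall-based centroids:
  length 8 mm, elevation 60° from the local tangent, radius 40–60 % of the
  parent, attachment points stratified along the middle 70 % of the arc
  with golden-angle azimuth spacing so branches never merge. The analytic
  arc is the reference centerline and its endpoints are the seeds.
* **`make_stenosis_phantom()`** — a gently curved 60 mm tube (150 mm radius
  of curvature) carrying one stenosis (radius factor 0.5) and one dilation
  (factor 1.5), each 10 mm long with 2 mm cosine tapers, at randomized
  non-overlapping arc positions returned as ground truth.

Rasterization stamps spheres along the axis at quarter-voxel spacing, which
reproduces a tube's cross-section area to within a few percent of πr² and
errors out (naming the tube) if any part leaves the grid. Noise-free output
is bit-identical across seeds; with noise, output is bit-reproducible for a
fixed seed.

**What the phantoms do not emulate** — and hence what passing tests do not
establish about patient data: beam hardening, motion, partial-volume
blurring at real scanner resolution, heterogeneous tissue TACs, recirculation,
anatomically realistic vessel trees, or imperfect registration. The phantom
suite validates the geometry and signal-processing machinery under
controlled conditions, not clinical image quality.

# Validation suites and problem sizes

`validate_centerline_accuracy()` generates ten phantoms per branch count
(0/3/6) at 0.5 mm spacing, extracts each centerline between the analytic
endpoints with 1 mm slice steps, and pools point-to-analytic-axis distances
over the whole suite (point-to-segment distances against the densely
sampled arc, so no resampling artefact enters). `validate_caliber_localization()`
generates twenty stenosis/dilation phantoms, straightens each mask with
0.5 mm steps, and counts a phantom as correct when the minimum-area slice
falls inside the true stenosis interval and the maximum-area slice inside
the true dilation interval, after aligning arc length by projecting the
extracted path's start onto the analytic axis. These sizes keep a full run
in the minutes range on a single core while exercising every code path;
`scripts/acceptance.R` reruns both suites from scratch at a caller-chosen
seed and writes the three headline quantities as JSON.

# Known limitations

* The marching initialization assumes the seed chord points roughly along
  the vessel; a vessel segment subtending much more than a half-turn
  between seeds should be extracted in pieces.
* Artery/vein separation assumes a bimodal TTP histogram. Pathologies that
  merge the modes (e.g. arteriovenous shunting) will trigger the unimodal
  error and require a manual `v_ttp`.
* The FG threshold default (Otsu on log FG) assumes vessels and enhancing
  tissue form separable modes; extremely low-dose, high-noise series may
  need an explicit threshold.
* Straightening assumes the centerline is simple (no self-intersection)
  and the plane half-size is below the local radius of curvature; both
  hold for the intended cerebral vessels at the default 6 mm half-size.
* Registration is out of scope: frames are assumed aligned.
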