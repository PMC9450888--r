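---
title: "Methods: quantifying nuclear repair foci in expansion microscopy"
author: "exmfoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nuclear repair foci in expansion microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters and numerical choices
behind `exmfoci`. The package analyses expansion-microscopy (ExM) images
of nuclear DNA-damage foci: it quantifies how much and how evenly a
nucleus expanded, detects and classifies the sub-structures formed by
repair proteins (a core channel such as BRCA1 or RAD51 surrounded by
partner accumulations such as 53BP1), and measures the averaged nanoscale
geometry of the encapsulated "core + shell" class.

## Units, frames and conventions

All internal coordinates and lengths are nanometres; micrometres appear
only at I/O and in reports. Every length carries a *frame*:
`post_expansion` (what the microscope measures on the expanded gel) or
`pre_expansion` (the biological scale). Conversion divides or multiplies
by the linear expansion factor; the default reporting factor is 4.0, the
macroscale gel expansion, because the printed pre-expansion equivalents
of all post-expansion measurements are consistent with dividing by 4
(rather than by the volume-derived 3.7). Areas scale as the square and
volumes as the cube of the linear factor, so the factor extractors take
the square root of an area ratio and the cube root of a volume ratio.

Voxel convention (fixed everywhere): 0-based voxel `i` spans
`[i, i+1) * voxel_size`, so its centre is `(i + 0.5) * voxel_size`; in
R's 1-based indexing element `j` has centre `(j - 0.5) * voxel_size`.
Array axes are ordered (x, y, z). Structure crops are cubes with an odd
voxel count per axis so that the structure core occupies the exact
central voxel; a requested 5 µm edge at 100 nm voxels therefore yields a
51³ crop. The 5 µm default crop edge reads the crop-box size as an edge
length, not a volume: encapsulated structures span ~4–5 µm
post-expansion, so a cube of volume 5 µm³ (edge 1.7 µm) could not contain
one.

## The synthetic-scene generator

No public image data accompany this analysis, so the generator is a
first-class module: it emulates the features of the real experiments
that the downstream code is sensitive to, and plants exact ground truth.

A scene is built in the pre-expansion frame: an ellipsoidal nucleus
(default semi-axes 3.2 × 2.6 × 1.7 µm — a scaled-down nucleus chosen to
keep default volumes at 96² × 48 voxels; the geometry, not the absolute
size, is what the pipeline measures), an S-phase-style DNA texture
(early = diffuse fine speckle, mid = patchy interior blobs, late =
peripheral blobs; purely cosmetic staging — classification never reads
the DNA channel), and focus structures planted at dart-thrown positions
with a minimum separation of 4.2 µm (post frame) so that no partner spot
can attach to two structures. Expansion maps every coordinate through a
true similarity `y = s R x + t` (default `s = 4`, random rotation about
the optical axis) plus an optional band-limited random displacement
field: a sum of 4 sinusoidal harmonics per component with wavelength set
by `distortion_scale_nm`, scaled so the field's RMS magnitude equals
`distortion_amplitude_nm`. Amplitude 0 gives a perfect similarity, which
is what the isotropy-null tests rely on; the true transform is returned
for recovery scoring.

Structure geometry is stated in post-expansion nm (the frame the
detector sees) and divided by the expansion factor when planting:

* class 1: one core (site-channel) spot; class 2: core + one partner
  spot at 0.6–1.8 µm; class 3: 2–3 site spots (regular polygon of radius
  240 nm) + one partner; class 4: multiple site + 2–3 partner spots at
  0.7–1.6 µm; class 5: one core encapsulated by 3–8 partner satellites
  on a shell of radius 650 nm (±3 % radial jitter).
* Satellites are placed on a randomly rotated spherical Fibonacci
  lattice ("shell", the default) or on a planar ring with a controlled
  tilt ("ring") — the ring arrangement exists because the averaging
  workflow selects structures whose shell lies parallel to the focal
  plane. The 650 nm default shell radius makes the expected profile
  peak-to-peak 1.3 µm, the scale of the real averaged structures; the
  3–8 satellite range reflects the spot-like shells seen in such data
  and is configurable.
* The 240 nm multi-site polygon radius keeps sibling core spots within
  one cluster (pairwise 415–480 nm) yet above 4 lateral PSF sigmas.

Rendering: each punctum becomes an anisotropic Gaussian (the standard
PSF surrogate; defaults σ = 100 nm lateral, 300 nm axial post-expansion,
60/180 nm for the sharper pre-expansion acquisition), peak amplitude
2000 photons (±20 %), on a background of 20 photons outside and +200
inside the nucleus, followed by Poisson noise and Gaussian read noise
(σ = 2). A planting-time gate resamples any draw whose same-channel
spots fall closer than 4 PSF sigmas (in sigma-scaled distance), so
"resolvable preset" claims are enforced by construction; the gate can be
disabled to plant deliberately unresolvable geometries such as the
contracted shell. Every planted structure is re-classified from its
exact coordinates at generation time and redrawn if it violates its own
class rule, so ground-truth labels are correct by construction. The DNA
texture blobs are rendered at 3× the PSF width — they model chromatin
domains, not puncta.

What the generator does **not** emulate: SIM reconstruction artefacts,
deconvolution residuals, gel refraction, autofluorescence, spot
brightness/size distributions of real antibody staining, or nuclei
whose expansion is locally anisotropic beyond the smooth harmonic field.
Passing recovery tests on these scenes therefore demonstrates the
correctness of the measurement chain, not the biology-facing robustness
of any particular threshold on real data.

## Segmentation

The 2D route mirrors an area-measurement workflow: background via
grayscale opening with a disc (the morphological equivalent of a
rolling-ball background; radius configurable, historically chosen per
dataset), an *explicit* threshold (the original workflow used a manually
determined one; Otsu is available behind `otsu_fallback`), connected
components, and area filters that drop features too small to be nuclei
or merged multi-nucleus blobs. Default bounds derive from an expected
nuclear diameter assuming circularity: `[0.25, 4] ×` the implied circle
area. The 3D route: a single global Otsu threshold (the whole stack is
presented to Otsu as one histogram), binary erosion then dilation with a
radius-1 voxel ball (the element is stated nowhere in the source
workflow; radius-1, one iteration, is the mildest choice and is
configurable), hole filling by border-connected background labelling,
and 6-connected component labelling. Expansion factors use the ratio of
*mean* per-nucleus area or volume, then the square/cube root.

## Registration and isotropy

Horn's closed-form quaternion solution fits the least-squares similarity
between matched pre/post control points: rotation from the largest
eigenvector of the 4×4 quaternion matrix of the cross-covariance, scale
from the rotation-consistent least-squares estimate, translation from
the centroids. Noiseless similarity-related point sets are recovered to
machine precision (the suite checks ≤ 1e-9 relative error, including at
scale 4 — the regime of a real pre/post pair). The 80/20
train/validation split is seeded-random (`round(0.8 n)` train; 21 points
give 17/4); the source workflow does not state its selection rule, so
the seed is recorded in the report. The reported "MSE" is the **mean
Euclidean distance in nm** between matched points — the quantity is
reported in nm in this field, which a squared error (nm²) could not be;
the squared variant sits behind `squared = TRUE`. Validation error
exceeding training error is the expected overfitting direction and is
verified on noisy simulations. Isotropic resampling uses separable Keys
cubic convolution (a = −0.5) per axis, which reproduces linear ramps
exactly away from borders; an upsampling factor above 50 per axis is
refused as a memory guard. `pairwise_distance_table` compares all
n(n−1)/2 control-point distances pre vs post/factor; under pure scaling
every deviation is zero, and the maximum absolute deviation grows
monotonically with planted distortion amplitude.

## Spot detection, clustering, classification

Detection is TrackMate-style: smooth with a per-axis Gaussian of
σ = r/√3 (the standard blob-scale calibration converting an expected
radius r to the LoG scale; applied per axis in voxels so anisotropic
sampling is handled), take the negated scale-normalised Laplacian
(Σ σ² ∂²/∂u², positive for bright blobs), find local maxima within a
radius-sized box neighbourhood, keep maxima whose response — the spot
quality, a prominence measure since the band-passed background is
zero-mean — reaches the threshold, and refine each by a 3-point
quadratic fit per axis (offsets clamped to ±0.5 voxel). Ties are broken
by lexicographic voxel index, making detection fully deterministic. The
radius must be at least one voxel per axis; with very anisotropic voxels
this couples the choice of radius to the axial sampling (the demo scene
at 400 nm axial voxels must detect at r = 400 nm, where two core spots
480 nm apart fall inside one suppression box and merge — the reason the
finer-sampled recovery scenes use r = 250 nm).

Clustering of site-channel spots is exactly fixed-radius connected
components: edges between all pairs at distance ≤ link radius,
implemented with a spatial grid hash plus union-find and verified in the
tests against a brute-force partition of the full distance matrix (and
against single-linkage hclust cut at the radius, which defines the same
partition). The cluster core is the unweighted centre of mass. Partner
spots within the 2 µm search radius of a core are attached; a spot in
reach of several cores attaches to each and is flagged `shared`. The
default link radius (500 nm) reflects the sub-cluster scale of site-spot
accumulations; recovery runs against the generator's multi-site geometry
use 600 nm, above the planted 480 nm spacing plus localisation error.

Classification makes the verbal class definitions operational as count
predicates over (site count, partner counts, encapsulation), shipped as
editable YAML rule tables that are validated for exhaustiveness and
mutual exclusivity over the reachable count grid before use.
"Encapsulated" is nowhere defined geometrically in the source workflow
(classification there was manual, from presented crops — a manual mode
via exported crops and a hand-label CSV is retained); here it means: at
least 3 satellites whose 3D convex hull contains the core, computed by
exact supporting-plane enumeration (satellite counts are small, so the
O(n⁴) test is negligible and is verified against Carathéodory
tetrahedron enumeration). Near-coplanar satellite sets (third singular
value < 1e-6 of the first) fall back to angular coverage ≥ 180° around
the projected core in the satellites' best-fit plane. One-core
structures with multiple partners that *fail* encapsulation fall to
class 4 — the five classes must be exhaustive and class 4 (multiple
spots of both proteins) is the least-wrong bucket; the assignment is
isolated in the rules file. Site-only clusters of any multiplicity are
class 1 ("core spots only"). The ten-class three-channel taxonomy
(RAD51 defined as the centre) is a reconstruction: the enumeration over
(RAD51 single/multiple) × (53BP1 absent/single/multiple) × (BRCA1
absent/present), with encapsulation splitting the all-multiple cell,
satisfies every pinned definition (class 4 = multi-RAD51 +
multi-53BP1 without BRCA1; classes 7–9 contain all three; class 9 =
multi-RAD51 with BRCA1 encapsulated by multi-53BP1) and is shipped as
`inst/extdata/rules_three_channel.yaml` for editing.

Distance subclassification of encapsulated structures uses the *median*
core-to-satellite distance (mean/median is not pinned by the source
description; the median is robust to a single stray satellite and is
configurable) against bins reconstructed from the reported phenotypes:
contracted < 0.5 µm, control-like 1.8–2 µm, extended 2–2.5 µm, with the
intermediate 0.5–1.8 µm bin auto-filled; out-of-range distances go to an
overflow bin with a warning. The continuity test thresholds a structure
crop at half its maximum and asks whether at least two member-spot
centres fall in one connected foreground component.

## Averaging and radial profiles

Structures whose partner-spot best-fit plane (principal axes) is within
20° of the focal plane — the by-eye selection of the original workflow
replaced by an explicit, configurable tolerance — and whose core lies
within half a band width of that plane are cropped (core at the crop
centre), aligned by translation only (no rotational alignment is applied
because radial profiles are rotation-insensitive; the tests bound the
rotational discretisation error at < 2 % RMS) and averaged voxel-wise.
The radial profile bins central-slice pixels by
`floor(distance / band_width)`; a band's value is the mean intensity of
its pixels, so band-count-weighted profile sums conserve total slice
intensity exactly and profiling commutes with averaging (both are
linear). Band width defaults to 100 nm post-expansion (≈ 25 nm
pre-expansion at factor 4), giving ≥ 12 bands across an encapsulated
structure; it must be at least one pixel.

Peak-to-peak distance is defined as twice the radius of the profile's
global maximum band, refined by a 3-point quadratic fit over
neighbouring bands: a symmetric annular distribution has its two
opposite peaks at ±r through the centre, which makes the printed
1.27/1.43/1.92/1.75 µm scale quantities reproducible from a radial
profile. A profile whose maximum is the innermost band has no annular
peak — the contracted phenotype in which the central void is lost — and
returns 0 with the flag `"no annular peak"`. Spans are twice the
outermost radius at which a channel's profile reaches half (the
configurable `fraction`) of its maximum, interpolated linearly between
band centres; the gap is the shell's inner half-max edge minus the
core's outer half-max edge, clamped at zero so an overlapping shell
reads as "void lost".

## Problem sizes, tolerances, degenerate inputs

The test and acceptance workloads use sizes chosen to exercise every
code path at comfortable statistical power: 21-point registration sets
with 100 noisy replicates; 100 clustering scenes of 20–500 spots;
100–500 planted structures (rendered one per 56²×28 crop at
100/100/200 nm voxels) for classification recovery; one 96²×48-voxel
pre / 192²×96-voxel post nucleus for expansion-factor recovery; 10 seeds
× 6 rings for profile recovery. Degenerate inputs are first-class:
constant images are an explicit Otsu error and detect zero spots;
collinear control points are a rank-deficiency error; empty masks warn
rather than throw; flat profiles are an undefined-span error; planting a
shell of radius 0 with multiple satellites is a generation error.

Numerical tolerances: hull membership uses a relative tolerance of 1e-9
of the satellite scale; coplanarity 1e-6; quaternion norm 1e-9; the
quaternion angle metric uses the chord/asin form, which stays accurate
where `acos` of a near-unit dot product loses all precision.

## Known limitations

* The three-channel class enumeration beyond the textually pinned
  classes is a reconstruction; users with the authoritative scheme
  should edit the YAML rules file.
* Detection requires the spot radius to be ≥ one voxel per axis, which
  at very anisotropic voxels forces a large radius and can merge close
  same-channel spots (quantified above).
* The distortion field is smooth and band-limited; tear- or
  boundary-type expansion artefacts are out of scope.
* No uncertainty propagation on expansion factors or profile
  measurements; the package exports per-structure tables from which
  downstream statistics (e.g. mean ± s.e.m. across nuclei) can be
  computed.
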