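# exmfoci

Quantitative analysis of nuclear DNA-damage repair foci imaged by
**expansion microscopy (ExM)**.

ExM physically enlarges a fixed specimen ~4-fold in each dimension by
embedding it in a swellable polyelectrolyte gel, so that a conventional
diffraction-limited microscope resolves structures at an effective
~65–70 nm scale. Applied to the nucleus, this makes it possible to survey
tens of thousands of DNA-damage response structures — accumulations
("foci") of repair proteins such as BRCA1, 53BP1 and RAD51 — and to
quantify their internal nanoscale architecture. `exmfoci` implements the
full analysis chain for such experiments, together with a synthetic-scene
generator with planted ground truth so that every stage can be validated
end to end without microscope data.

## What the package computes

**Expansion-factor arithmetic** (`linear_factor_from_area_ratio`,
`linear_factor_from_volume_ratio`, `to_pre_expansion`): a nucleus whose
area grows 16-fold has expanded linearly by `sqrt(16) = 4`; a 52-fold
volume increase gives `52^(1/3) = 3.7`. Lengths measured post-expansion
divide by the linear factor *s* to give pre-expansion equivalents
(e.g. 1.27 µm / 4 = 0.32 µm).

**Nucleus segmentation** (`segment_nuclei_2d`, `segment_nuclei_3d`,
`expansion_factor_from_masks`): a 2D area route (rolling-ball-style
background subtraction, explicit threshold, area filters, boundary
tracing) and a 3D volume route (global Otsu, erosion/dilation, hole fill).
Mean per-nucleus area or volume ratios convert to linear factors.

**Isotropy via registration** (`fit_similarity_horn`,
`register_control_points`, `pairwise_distance_table`,
`resample_isotropic`): matched pre/post-expansion control points are fit
with a similarity transform `y = s R x + t` using Horn's closed-form
quaternion method, with an 80/20 train/validation split; the mean
Euclidean residual (nm) measures distortion the best similarity cannot
explain. Pairwise control-point distances compare `post/s` against `pre`
directly.

**Spot-based structure analysis** (`detect_spots`, `cluster_site_spots`,
`assemble_structures`, `classify_structure`): per-channel 3D
Laplacian-of-Gaussian detection with prominence (quality) filtering and
sub-voxel refinement; fixed-radius connected-component clustering of the
site channel (e.g. BRCA1); attachment of partner spots (e.g. 53BP1)
within a 2 µm search radius; and rule-based classification into the
five-class two-channel taxonomy (class 5 = one core spot encapsulated by
a shell of partner satellites) or the ten-class RAD51-centred
three-channel taxonomy, plus distance subclassification and a continuity
test.

**Structure averaging** (`select_in_plane`, `average_structures`,
`radial_profile`, `peak_to_peak`, `span_and_gap`): class-5 structures
oriented parallel to the focal plane are cropped, averaged voxel-wise,
and summarised by radial intensity profiles from which peak-to-peak
distances, channel spans and the core–shell gap are read.

**Synthetic scenes** (`simulation_config`, `plant_structure`,
`render_volume`, `simulate_expansion`, `generate_nucleus_scene`): seeded
S-phase-like nuclei containing structures of every class, Gaussian-PSF
blur, Poisson + Gaussian noise, and simulated ~4x expansion with an
optional smooth distortion field; ground truth (spots, class labels, true
transform) is returned for scoring.

**Pipeline** (`run_pipeline`, `make_report`): one config drives
simulate → segment → register → detect/classify → average → report, with
a checksummed manifest for reproducibility.

## Worked example

```r
library(exmfoci)

# one nucleus, two planted class-5 structures, full pipeline
run <- run_pipeline(demo_pipeline_config(seed = 5), "demo_out")
cat(make_report("demo_out"), sep = "\n")
```

Output from this exact call:

```
exmfoci pipeline report
=======================

Structure class frequencies:
  class 1: 1
  class 2: 2
  class 3: 0
  class 4: 1
  class 5: 2
  total: 6

Expansion: area ratio 16 (linear 4), volume ratio 64.1 (linear 4)
Registration: MSE 1.722e-12 nm train (n=112) / 1.819e-12 nm validation (n=28), scale 4
Class-5 average (n=2): peak-to-peak 1250 nm post (312.6 nm pre), core span 475.1 nm, shell span 2045 nm, gap 0 nm
```

Reading it: six structures were planted (classes 1–5); the measured
nuclear area/volume ratios (16 / 64.1) recover the simulated linear
expansion factor of 4; the noiseless control-point registration has
essentially zero residual at the true scale 4; and the averaged class-5
structures show a 53BP1 shell whose intensity peaks 1.25 µm apart
(≈ 0.31 µm pre-expansion — twice the planted 650 nm shell radius). One
planted class-3 structure is read as class 2 at this demo's coarse
(200 nm) voxels because its two core spots merge at the 400 nm detection
radius; the vignette discusses the resolution limits.

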