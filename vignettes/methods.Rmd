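---
title: "Methods: co-registering intraoperative OCT with histology of the cavity shaving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-registering intraoperative OCT with histology of the cavity shaving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The registration chain

Validating intraoperative (in vivo) OCT of the breast surgical cavity
against histology is indirect by necessity: histology exists only for the
excised cavity shaving, and the shaving deforms between excision, benchtop
imaging and sectioning. This package implements the two-stage chain that
bridges the gap:

* **Stage 1 — in vivo to ex vivo OCT.** In vivo volumes are acquired as a
  3 × 3 grid of partially overlapping 6 × 6 mm² scans centered on a cavity
  suture (nominal 5 mm probe steps, hence ~1 mm overlap, extending the field
  of view to ~15 × 15 mm²). The excised shaving is imaged on a benchtop
  system, with stage-translated tiles stitched into one wide-field volume.
  The suture — a bright elongated ridge that protrudes above the tissue
  surface and is visible in both frames — anchors the grid; each tile is
  then refined against the wide-field volume.
* **Stage 2 — ex vivo OCT to histology.** The shaving is bread-loafed into
  ~4–5 mm slabs *orthogonal to the en face plane*, so histology slides
  correspond to cross-sectional B-scans, never en face planes. Section
  lines are overlaid on the wide-field en face image, each slide is rescaled
  by its shrinkage correction factor, and the best-matching B-scan near each
  line is selected.

All data carriers are simple S3 records: `oct_volume` (a `[z, y, x]` array
of linear backscatter intensities plus voxel spacings in µm),
`scan_session`, `rigid_pose2d`, `en_face_plane`, `fiducial_mark`,
`stress_strain_curve`, `histology_section`, `elasticity_volume`.

# Surface-relative en face planes

Both registration stages compare *en face* planes sampled a fixed 100 µm
below the local tissue surface, because the probe and benchtop window
flatten the tissue differently and absolute depth is meaningless across
systems. The surface is detected per A-scan as the first depth at which the
axially median-filtered intensity crosses an adaptive threshold
(`intensity_floor_fraction = 0.3` of the column maximum), followed by
lateral median smoothing over 50 µm; columns below a robust global noise
floor are invalid. Depth sampling is nearest-voxel: the 100 µm offset is
~30 axial voxels at the instrument's 3.4 µm axial pitch, so axial
interpolation is immaterial.

# Suture detection

The cavity suture is a bright ridge of roughly known width (100–600 µm
acceptance band) that protrudes above the surface, so at 100 µm below the
surface it appears as the dominant elongated bright component.
`detect_suture()` runs grayscale top-hat filtering at the suture scale, a
hysteresis threshold (candidates are delineated at a weak level but must
reach a strong level somewhere; both levels are floored at 3 and 6 MAD
above background so a speckle-only plane cannot produce candidates),
morphological closing to bridge speckle gaps along the ridge, connected
components, and second-moment gating on elongation (≥ 3), width (the
acceptance band) and length (≥ 1 mm — sutures are millimeter-scale, which
separates them from chance alignments of bright speckle). When several
candidates pass — the long orientation suture can coexist with the short
cavity suture — the highest-confidence one is returned with a
`multiplicity` flag, leaving disambiguation to the caller and the session
notes. Detection is rotation-covariant, and confidence does not increase
with noise.

# Tile refinement

`refine_tile()` scores candidate poses by **masked normalized
cross-correlation** (a Padfield-style FFT formulation over all translations;
no-data pixels are excluded per shift) between dB-scaled, surface-flattened
en face planes. The search covers translation (default ±2000 µm), in-plane
rotation (±10°, refined to 0.5° by a coarse-to-fine grid) and the en face
sampling depth dz (±200 µm) — the automated counterpart of scrolling through
depth planes by eye; probe tilt is approximated by this dz search only, not
by full 3-D registration. Translation is refined to sub-voxel by a local
quadratic fit of the NCC surface. Ties break toward the smallest |θ|, then
|dz|, then displacement from the initial pose.

Two preprocessing choices matter:

* **dB scaling + NCC** makes the score invariant to the different intensity
  scales of the two instruments.
* **Plane smoothing (`plane_smooth_um = 120`)** matches the effective
  resolutions of the two systems and suppresses speckle. Speckle is
  uncorrelated between instruments (different point-spread functions), so
  without smoothing it acts as strong noise on both planes and the NCC
  ceiling for structure is low; with smoothing the score responds to tissue
  structure. The default is of the order of the inter-system resolution
  gap; values much beyond ~150 µm start to blunt the adipose/dense
  boundaries that drive mixed-tissue registration.

A tile whose valid overlap with wide-field data falls below 25 % of its
area is unregistrable (score −1). **Success** is an automated surrogate for
the two-rater agreement used clinically: NCC score ≥ 0.3 *and* mean
positional residual against adjacent placed grid neighbors ≤ 1500 µm. Both
thresholds are package defaults, not published constants; the consistency
gate is what rejects "decoy" optima that disagree with the grid, and it is
also the deliberate (documented) answer to tiles that do not overlap at
all — they are never silently dropped, merely reported with their flags and
gated by consistency.

# Tissue classification

A tile is labeled `dense` or `adipose` when more than 90 % of its valid
field of view is that type, else `mixed`. Per-pixel type uses the dB of the
locally averaged linear intensity (300 µm scale) against a threshold of
−5 dB. That threshold is calibrated to the phantom generator's reflectivity
scale, where dense stroma sits near 0 dB and adipose (area-weighted septa +
dark cell interiors) near −9 dB; on real instruments it must be recalibrated
to the system's intensity normalization. A ground-truth class map can be
supplied instead, which is how phantom studies score classification.

# Quantitative micro-elastography

The QME chain assumes a uniaxial series-spring model: at each lateral
position the compliant silicone layer and the tissue column share one axial
stress. `estimate_displacement()` tracks axial motion between the pre- and
post-compression volumes by windowed 1-D cross-correlation (default 50 µm
window) over integer shifts, then refines to sub-voxel with a
gradient-based (optical-flow) residual, falling back to a parabolic peak
fit outside its linear range. Intensity-based tracking is used throughout
(complex phase data are out of scope), which sets the precision floor: both
volumes receive a light axial Gaussian pre-smoothing (σ = 1 voxel) to
symmetrize interpolation blur between the states, which measurably reduces
integer-locking bias. Strain is the confidence-weighted least-squares slope
of displacement vs depth (default 100 µm fit window); layer strain is fit
over the interior 15–85 % of the layer band so the fit never crosses the
layer/tissue boundary. Stress follows by monotone interpolation of the
layer's stress–strain curve, elasticity is `E = σ / ε` with strains below
10⁻⁴ masked as invalid, and computation is in linear kPa (log scale is a
display convention only). Masking removes adipose regions (low OCT signal
produces elasticity artifacts) and non-contact columns (layer strain at the
noise floor); the mask is monotone in its thresholds.

The forward simulator (`simulate_compression_pair()`) implements exactly
this series-spring model — per-column stress solved by bisection of
`actuation = L·ε_layer(σ) + σ·∫dz/E(z)` — and warps the pre volume through
the resulting displacement field. Matching forward and inverse model
assumptions is intentional: phantom tests then isolate *estimation* error
(tracking, strain fitting) from *model* error, which the package does not
attempt to quantify.

# The phantom generator

The generator emulates the image features the pipeline depends on, not OCT
physics (no wave-optics or Monte-Carlo simulation):

* **Geometry** defaults to the clinical acquisition: 20 × 20 × 3.5 mm
  shavings at 12.7 µm lateral / 3.4 µm axial pitch (the instrument's
  6 mm / 474 px and 3.5 mm / 1024 px sampling). Tests and the shipped demo
  run the same generator at coarser sampling (typically 12 × 12 × 1.2 mm at
  60 µm / 20 µm, and 5 µm axially for QME) so the suite completes in
  minutes; the spatial frequencies of every feature are expressed in µm and
  are resolution-independent.
* **Tissue classes** come from a thresholded smooth random field hitting a
  target adipose areal fraction. Adipose is a jittered-grid Voronoi
  honeycomb (90 µm cells, bright ~18 µm septa at 0.40 reflectivity over
  0.04 interiors). Dense stroma has two-scale log-normal intensity
  variation (σ ≈ 1.7 dB at 500 µm and 1.5 mm scales) plus sparse
  hypo-reflective duct/lobule inclusions (5–7 % area, −7 dB). These choices
  realize the qualitative contrast structure the protocol relies on: dense
  tissue carries subtle but registrable intensity variation, adipose is
  statistically homogeneous beyond its cell scale, and class boundaries are
  the strongest features. The duct fraction is deliberately kept below 10 %
  so a pure dense field still satisfies the 90 % dominance rule.
* **Depth structure**: smooth surface topography (default 100 µm
  amplitude), class-dependent exponential attenuation (6 dB/mm dense,
  one-third for adipose), fully developed multiplicative exponential
  speckle (contrast 0.9), tubular vessel/nerve inclusions (dark lumen,
  bright wall at a depth band), and a suture rendered as a 280 µm-wide
  bright ridge protruding 150 µm above the surface with a 15 dB shadow
  beneath.
* **Elasticity truth**: dense 15 kPa, adipose 3 kPa, thermally damaged
  patches 25 kPa — plausible soft-tissue values in the range reported for
  diathermy-damaged dense tissue.
* **Acquisition degradations** for in vivo tiles: additive noise (tests use
  SNR 10 dB), lateral blur for the resolution gap (80 µm), a blood film
  (uniform attenuation), probe tilt (a linear ramp of sampled depth across
  the tile), and — important for honest registration statistics —
  *speckle replacement* (`respeckle_contrast`): the two instruments observe
  independent speckle over the same tissue, so the tile's speckle is
  regenerated after blurring. Without this, tiles carved from the same
  simulated volume share their speckle realization and even featureless
  adipose registers perfectly, which real cross-system data do not do.

What passing phantom tests does **not** show: robustness to real blood
pooling and surface debris, to non-rigid cavity deformation between scans,
to specimen regions outside the ex vivo imaging depth, or to the intensity
calibration differences of real instruments. The phantom's realism is
qualitative by design.

# Numerical and design choices

* **Determinism**: every generator is a pure function of its `seed`; the
  pipeline fans one seed out to fixed per-stage sub-seeds, and the same
  seed reproduces `summary.json` byte-identically.
* **Storage**: OCT volumes are multi-page TIFF stacks (z-ascending pages)
  with a JSON metadata sidecar. Integer data up to 16 bits round-trip
  bit-exactly; other data are stored as 32-bit float pages normalized by a
  recorded scale (round-trip to single precision).
* **Stitching** trusts stage positions (no cross-tile re-registration),
  requires a common voxel lattice, and feather-blends overlaps with weights
  that sum to 1 wherever any tile contributes; the default feather width is
  half the smallest overlap.
* **Coordinates**: `[z, y, x]` arrays, 1-based voxel centers at
  `(i − 1) · spacing`; a tile's pose refers to its center pixel
  `floor(n/2) + 1`, so voxel-multiple translations at θ = 0 are exact
  lattice crops (this makes the zero-degradation identity contract exact
  rather than approximate).
* **Degenerate inputs**: all-zero volumes raise a no-surface error; an en
  face plane with under 50 % valid area refuses suture detection and
  classification; layer strains outside the characterized stress–strain
  range raise an error unless extrapolation is explicitly enabled (then
  flagged); zero-strain voxels are masked, not divided by.
* **Histology warp is not inverted.** Sections are rescaled rigidly by the
  per-slide factor `c = fresh width / section width` (one factor per slide;
  within-slide variation is not modeled) and matched by binary
  structure-map Dice, mirroring the expert practice of scanning nearby
  B-scans rather than deforming the slide. Fresh width is measured from the
  imaged specimen extent.
* **B-scan matching** reduces both images to binary solid-vs-void structure
  maps before Dice overlap because histology and OCT intensities have
  unrelated semantics; structure is what experts compare.

# Problem sizes used by the shipped checks

The test-suite and acceptance script run, per invocation: twenty
12 × 12 × 1.2 mm pose-recovery phantoms (200 × 200 × 60 voxels each) plus
six per tissue class for the success-ordering batch; two
3 × 3 × 1.5 mm QME phantoms at 5 µm axial pitch (50 × 50 × 300);
ten 9 × 9 × 0.9 mm histology phantoms; and one full 20 mm demo pipeline.
These sizes were chosen so the complete suite runs in roughly a quarter
hour on a single CPU while every check still operates at clinically
meaningful physical scales.

# Known limitations

* Intensity-correlation displacement tracking is noisier than the
  phase-sensitive detection used by real QME hardware; recovered absolute
  moduli in layered media carry a systematic few-tens-of-percent bias
  (ratios are accurate), and the homogeneous-phantom recovery is the
  calibrated case.
* The classification threshold is generator-calibrated, not
  instrument-calibrated.
* Only yaw is searched; out-of-plane tilt is approximated by the depth
  (dz) search, as in the manual protocol.
* The success gate is a surrogate for inter-rater agreement; its two
  thresholds are defaults to be tuned per instrument pair.
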