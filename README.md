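# octcoreg

Co-registration of intraoperative (in vivo) optical coherence tomography
(OCT) of the breast surgical cavity with histology of the excised cavity
shaving, using a wide-field ex vivo OCT scan of the shaving as intermediary.

## The problem

Handheld OCT probes can image the wall of the surgical cavity during
breast-conserving surgery, but validating what they see requires histology —
and histology is only available for the tissue that is subsequently excised
as a *cavity shaving*. Relating a 6 × 6 mm² in vivo OCT scan to a 4 µm
histology slide cut from that shaving is a chain of co-registration
problems. This package implements that chain, for tool builders and imaging
scientists who need an automated, testable version of the workflow:

1. **Grid acquisition.** Nine in vivo volumes are acquired in a 3 × 3 grid
   of partially overlapping scans centered on a cavity suture (~5 mm probe
   steps with a 6 mm field of view, hence ~1 mm overlap), extending the
   effective field of view to ~15 × 15 mm².
2. **Wide-field ex vivo imaging.** The excised shaving is scanned on a
   benchtop system at multiple stage positions and stitched
   (feather-blended) into one wide-field volume.
3. **In vivo → ex vivo registration.** The cavity suture, a bright
   elongated ridge visible in both frames at 100 µm below the tissue
   surface, anchors the grid; each tile is then refined by masked
   normalized cross-correlation (NCC) of surface-flattened en face planes
   over translation, in-plane rotation, and a depth-plane (dz) search.
   Success is assessed per tile from the NCC score and consistency with the
   grid, and summarized per tissue type (dense / adipose / mixed under a
   90 % field-of-view dominance rule).
4. **Ex vivo → histology.** Bread-loaf section lines are overlaid on the
   wide-field en face image, each section is rescaled by its shrinkage
   correction factor `c = fresh width / section width`, and the
   best-matching B-scan near each line is found by binary structure (Dice)
   matching.
5. **Quantitative micro-elastography (QME).** From a pre/post compression
   pair, axial displacement is tracked by windowed cross-correlation with
   gradient-based sub-voxel refinement, axial strain is the local slope of
   displacement vs depth, stress comes from a pre-characterized compliant
   layer, and elasticity is `E = stress / strain` per voxel, with adipose
   and non-contact artifacts masked.

No clinical data ships with the package: a synthetic phantom module
generates wide-field shavings with known ground truth (tissue classes,
suture, surface topography, elasticity, histology sections), so every stage
is exercisable and testable end to end.

## Worked example

```r
library(octcoreg)

res <- run_pipeline(pipeline_config(), out_dir = "demo_out", seed = 42)
res$summary_table
#>   tissue_class n_scanned pct_of_total n_coregistered success_pct
#> 1        dense         0            0              0           0
#> 2      adipose         0            0              0           0
#> 3        mixed         9          100              9         100
#> 4          all         9          100              9         100
round(res$mosaic$mean_pose_error_um, 1)
#> [1] 16.1
round(res$qme$median_dense_kpa, 1)   # ground truth: 15 kPa dense tissue
#> [1] 13.4
```

The demo generates a 20 × 20 × 1.5 mm phantom shaving (60 µm lateral /
20 µm axial sampling), extracts a 3 × 3 grid of degraded in vivo tiles
(noise, resolution blur, independent speckle), registers them back through
the suture anchor + NCC refinement (all nine succeed with scores 0.69–0.85;
mean placement error ~16 µm, a quarter of a voxel), maps bread-loaf
histology sections with a 1.18 shrinkage factor, and recovers dense-tissue
elasticity within ~11 % of the ground truth. `demo_out/` receives
`placements.json`, a per-class `summary.csv`, `histology.csv`,
`elasticity.tif` and a `composite.png` overlay of tile outlines on the
wide-field en face image.

A thin command-line front end wrapping the same functions is installed at
`inst/cli/coreg.R` (subcommands `phantom`, `stitch`, `mosaic`, `qme`,
`histmap`, `run`).

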