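Package: octcoreg
Title: Co-Registration of Intraoperative OCT with Wide-Field Ex Vivo OCT
    and Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating handheld in vivo optical coherence
    tomography (OCT) of the breast surgical cavity against histology of
    the excised cavity shaving, using a stitched wide-field ex vivo OCT
    volume as intermediary. In vivo tiles acquired in a 3x3 partially
    overlapping grid are anchored on a cavity-suture fiducial, refined by
    masked normalized cross-correlation of surface-flattened en face
    planes with in-plane rotation and depth-plane search, and summarized
    by tissue type. Includes quantitative micro-elastography (axial
    stress from a pre-characterized compliant layer divided by local
    axial strain), bread-loaf histology mapping with per-section
    shrinkage correction and B-scan matching, and a synthetic tissue
    phantom generator so that the full pipeline is exercisable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
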