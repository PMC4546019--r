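Package: muinpaint
Title: Inpainting of Metal-Implant Signal Voids in MR-Based PET Attenuation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting dental metal-implant signal voids in MR-derived
    PET attenuation maps (mu-maps) and for quantifying the attenuation-correction
    bias they cause. Provides a seeded head/neck phantom generator with injectable
    artifact voids of the two topological classes (enclosed and boundary-breaching),
    a 2-D parallel-beam attenuated projection simulator with ordinary-Poisson
    OSEM reconstruction, void detection and inner/outer classification, a
    two-channel Chan-Vese level-set contour closer driven by the non-attenuation-
    corrected PET image, atlas-based oral-cavity template masking with the
    80%/10% completion/reversal fill policy, and SUV bias metrics (relative and
    absolute differences, Wilcoxon matched-pairs testing, cohort summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
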