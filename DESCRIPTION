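Package: optomotor
Title: Compound-Eye Optics Reconstruction and Optomotor Response Analysis for
    Miniature Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for walking optomotor experiments on miniature
    insects with highly reduced compound eyes. Reconstructs per-ommatidium
    geometry (lens diameter, visual axes, interommatidial angles) from
    digitized 3-D landmark tables, derives thin-lens optics (radii of
    curvature, focal length, acceptance angle), scores optomotor turning
    responses from rotating-drum walking trajectories, evaluates a closed-form
    Reichardt elementary-motion-detector (EMD) model, and estimates the
    detector's temporal low-pass time constant by grid-search least squares.
    Includes synthetic-data generators for eye landmark sets, walking
    trajectories, and tuning-curve datasets so that the full pipeline is
    testable without microtomography or video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
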