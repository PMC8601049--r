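Package: linguakin
Title: Regional Tongue Deformation and Jaw Kinematics from 3D Marker
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for marker-based X-ray Reconstruction of
    Moving Morphology (XROMM) recordings of feeding: rigid-body pose
    estimation of skull and jaw from implanted markers, zero-phase
    low-pass filtering, jaw-pitch (Rz) extraction, gape-cycle
    segmentation with acceleration-based fast/slow phase classification,
    regional tongue length and width deformation metrics normalized to a
    CT rest configuration, per-cycle deformation magnitudes and circular
    timing statistics on standardized cycle time, and stratified
    permutation comparisons between behaviors (chewing versus drinking).
    Includes a synthetic-kinematics generator with analytic ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
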