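Package: neuroplanr
Title: Connectivity-Weighted Eloquence Scoring and Neurosurgical Trajectory Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multimodal "eloquence" scores for grey-matter regions and
    white-matter streamlines from functional and structural connectivity
    matrices (node strength, i.e. unsigned weighted degree), models a surgical
    access trajectory as a capsule-swept tube, extracts the grey-matter voxels
    and streamlines the tube intersects, and exhaustively searches entry points
    on a head-enclosing box to produce a colour-mappable risk map of total
    connectional damage per candidate trajectory. Includes a seeded phantom
    generator (parcellation, streamline bundles, consistent connectivity
    matrices) so the full pipeline is testable without patient data, plus
    trajectory comparison metrics (path length to the cortical boundary,
    Euclidean distance between entry points, angular distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
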