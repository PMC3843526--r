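Package: qsdar3d
Title: Consensus PLS and Tanimoto-KNN Modeling of 3D Spectral
    Data-Activity Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements the 3D-QSDAR (three-dimensional quantitative
    spectral data-activity relationship) workflow for modeling biological
    activity of small molecules from pairs of 13C chemical shifts
    augmented with inter-atomic distances.  Fingerprints are tessellated
    into regular bins of configurable granularity, and the resulting
    occupancy matrices are modeled by a SIMPLS partial least squares
    engine on standardized descriptors and by a Tanimoto-similarity
    weighted k-nearest-neighbors engine on raw occupancies.  Composite
    models aggregate many seeded randomized train/hold-out cycles with
    Y-scrambling, convergence and matched-pair orthogonality diagnostics;
    consensus models average predictions of two composite models.
    Interpretation back-projects the most frequently extracted
    positively and negatively weighted bins onto the contributing atom
    pairs.  Includes a fully seeded synthetic-data generator and a
    packaged table of aryl hydrocarbon receptor binding data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
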