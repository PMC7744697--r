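Package: idsim
Title: Similarity-Based Individual-Differences Analysis of Neural Response Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating inter-subject similarity in regional brain
    activity patterns to similarity on trait and message-evaluation measures.
    Builds Manhattan-ball region-of-interest masks around peak coordinates,
    extracts per-subject voxel patterns, converts subject-level measures into
    pairwise (dis)similarity vectors, and fits per-region round-robin
    distance-matrix regressions that partition explained variance into unique
    (delta R-squared), shared, and participant-intercept components.
    Inference uses a subject-level permutation scheme that respects the
    dyadic non-independence of pairwise similarities; regions are profiled by
    Ward clustering of probit-transformed pseudo p-values with empirical-Bayes
    shrinkage of cluster means. A synthetic-cohort generator with known
    ground truth supports calibration and parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml
Config/testthat/edition: 3
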