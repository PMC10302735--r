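Package: psamnmf
Title: Post-Stroke Severity Assessment by Consensus Clustering with
    Symmetric Nonnegative Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised severity assessment of upper-limb motor impairment
    from wearable (IMU) or camera-based motion recordings. Extracts
    frequency-domain position and acceleration features from 3D kinematic
    trials, clusters them with an eight-method ensemble (fuzzy C-means,
    k-means, self-organizing map, Gaussian mixture, DBSCAN, hierarchical,
    spectral, OPTICS), fuses the ensemble through a modified symmetric
    nonnegative matrix factorization of the co-association matrix (with
    CSPA, MCLA, HBGF and HGPA comparison solvers), labels consensus clusters
    by compensatory trunk displacement, and scores the result against
    severity classes derived from the Fugl-Meyer upper-extremity scale.
    Includes a synthetic cohort generator for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    mclust,
    kernlab,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
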