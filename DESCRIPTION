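Package: dgmap
Title: Directed Graph Mapping of Cardiac Activation for Reentry and
    Focal-Source Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds directed activation networks from multi-needle
    electrode geometries and local activation times, detects reentrant
    circuits as closed cycles in merged time-shifted graphs, condenses
    duplicate loop detections into distinct reentries with density-based
    clustering, classifies holo- and bi-ventricular macro-reentry by
    winding number, detects and verifies focal sources from electrogram
    morphology, and characterizes tachycardia episodes statistically
    (simultaneous-loop profiles, truncated-binomial spatial randomness,
    exact Mann-Whitney group comparison). A synthetic-data module
    generates needle-grid recordings with known focal, planar, rotor and
    macro-reentrant ground truth so the full pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
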