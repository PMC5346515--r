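Package: icga
Title: Graph Analysis of Independent Component Networks from Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds one weighted graph per intrinsic connectivity network from
    a single-subject ICA decomposition of resting-state BOLD fMRI. Regional
    time courses are regressed on component time courses, the resulting
    t-values are turned into edge weights by a min-based scheme with separate
    correlation and anti-correlation flavors, edges are thresholded at twice
    the Student-t significance cutoff, and subject graphs are aggregated into
    group graphs by an edge-presence rule. Includes template matching for
    component-to-network assignment, a pluggable neuronality classifier, a
    whole-brain "classical" network built from the artifact-cleaned signal,
    a graph-metric battery (edges, degree, triangles, clustering, path
    length, small-worldness with Erdos-Renyi nulls), ANOVA with Tukey HSD
    network comparison, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
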