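Package: flowscope
Title: Flow-Based Communities and Roles in Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-resolution community detection in directed weighted
    networks via Markov Stability of a teleported continuous-time random
    walk, with tools for comparing directed and symmetrized analyses,
    computing personalized interest distances from a vantage node,
    discovering flow roles through role-based similarity of incoming and
    outgoing walk counts combined with a relaxed minimum spanning tree
    graph, and classifying communities by their mix of roles. Includes
    synthetic generators with planted community and role structure so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    cluster,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
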