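Package: facpin
Title: Fast Agglomerative Clustering of Protein Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Community detection in weighted protein interaction networks
    (PINs) by fast agglomerative clustering around high-degree hubs. The
    merge criterion is the relative vertex-to-vertex clustering value, an
    asymmetric local similarity premetric that scores how much of one
    vertex's augmented neighborhood is shared with another's, optionally
    weighted by interaction reliability. Includes weighted partition
    quality functions (Newman modularity Q, the log-weighted variant, and
    modularity density D), comparator edge-clustering criteria, validation
    metrics against known protein complexes and functional categories
    (overlap score, sensitivity/specificity/F-score, recall/precision/
    F-measure), a planted-partition PIN simulator with reliability weights
    and spurious-edge noise, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), igraph, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
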