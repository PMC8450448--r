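Package: mrfmsc
Title: Multi-Smooth-Representation Fusion for Multi-View Spectral Clustering
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-omics sample clustering by graph-regularized self-expressive
    ("smooth") representation learning per omics view, auto-weighted fusion of
    the per-view similarity graphs into a consensus graph, and rank-constrained
    spectral embedding so the fused graph decomposes into exactly k connected
    components. Includes per-view KNN affinity graph construction, closed-form
    and Sylvester-equation solvers for the smooth-representation block update,
    adaptive view weighting that down-weights uninformative omics layers, a
    synthetic multi-view data generator with known cluster structure, clustering
    quality metrics (adjusted Rand index, normalized mutual information, mean
    silhouette) and silhouette-based screening of the number of clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), mclust, igraph, cluster, jsonlite, optparse,
    yaml, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Clustering, GraphAndNetwork, Network, Software
RoxygenNote: 7.3.3
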