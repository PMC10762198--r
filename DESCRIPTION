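Package: pelagicnets
Title: Sample-Specific Microbial Association Subnetworks Across Ocean Regions and Depths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to carve sample-specific subnetworks out of a single static
    microbial association network and study their biogeography. Implements
    compositional (centered log-ratio) preprocessing of amplicon ASV tables,
    removal of environmentally-driven edges by combining interaction
    information (with a permutation test) and the data-processing inequality,
    per-sample subnetwork derivation under a region- and depth-specific
    Jaccard co-occurrence condition, spatial prevalence classification of
    associations (global, prevalent, low-frequency, regional), vertical
    first-appearance profiles, per-subnetwork topology metrics, a
    graphlet-based label-free network dissimilarity with minimum spanning
    tree and density-based clustering, and a synthetic multi-region,
    multi-depth dataset generator with a planted-truth ledger so the whole
    pipeline is testable without downloading ocean survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
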