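Package: ablineage
Title: Antibody Lineage Structural Divergence and Binding-Mechanism Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing structural divergence within antibody
    lineages. Assigns antibody heavy-chain variable domains to germline
    V-gene lineages by pairwise alignment, applies Kabat numbering and CDR
    annotation, maps somatic mutations, superposes structures by the Kabsch
    algorithm and summarises CDR RMSD statistics, detects antibody-antigen
    hydrogen bonds and their occupancy across trajectory frames, clusters
    bound and free conformational ensembles with a fixed-radius (kclust
    style) scheme, and classifies each antibody's binding mechanism as
    conformational selection or induced fit. A synthetic-data module
    generates germline repertoires, mutated lineages, toy Fv scaffolds,
    conformer ensembles and interface trajectories with known ground truth
    for testing the full pipeline without molecular-dynamics input.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
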