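Package: netpharm
Title: Network-Pharmacology Analysis of Compound-Target-Disease Relationships
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A local, reproducible network-pharmacology pipeline for
    relating screened natural-product metabolites to disease genes:
    Lipinski rule-of-five and oral-bioavailability screening, provenance-
    tagged target-set algebra (Venn intersections across compound and
    disease sources), protein-protein interaction hub ranking by Maximal
    Clique Centrality, Maximum Neighborhood Component and Degree,
    mushroom-compound-target network assembly and degree prioritization,
    hypergeometric gene-set enrichment with Benjamini-Hochberg FDR control
    and rich-factor reporting, frontier-molecular-orbital reactivity
    descriptors (HOMO-LUMO gap, chemical hardness and softness), and
    docking-score comparison against reference ligands. Seeded synthetic-
    data generators with planted, recoverable structure replace all web
    databases so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
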