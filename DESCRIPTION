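Package: longevnet
Title: Network-Based Prioritization of Tumor Suppressor Orthologs as
    Candidate Longevity Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline protein-protein interaction network pipeline for
    guilt-by-association prioritization of candidate longevity genes in
    Caenorhabditis elegans. Reconstructs first-neighbour networks around
    aging and tumor-suppressor-ortholog seed lists from curated
    interaction tables, merges them and partitions the merged network
    into the eight Venn clusters of the aging/TSG overlap, ranks
    candidate genes by the sum of their degree and betweenness ranks,
    estimates a-priori probabilities of hitting lifespan-reduction
    genes, performs Gene Ontology over-representation of a seed gene's
    secondary neighbourhood (Fisher's exact test with Benjamini-Hochberg
    FDR) and Wang-style GO semantic-similarity filtering, and emulates
    the OrthoMCL orthology stage offline via reciprocal best hits plus
    Markov clustering. Ships seeded synthetic-data generators with
    planted ground truth for every input format (interaction TSV,
    XGMML, OBO, GAF, BLAST tabular).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
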