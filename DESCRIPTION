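Package: degnet
Title: Gene-Set-Conditioned Interaction-Network Hub Analysis with DEG
    Calling and TAP-MS Specificity Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for studying a transcriptional and
    proteomic stress response: per-gene factorial (3-way) ANOVA with fold
    change and p-value filters to call differentially expressed genes,
    Venn partitioning of gene and protein sets with overlap percentages,
    hypergeometric gene-family overrepresentation tests,
    set-conditioned degree (hub) analysis of a protein-protein
    interaction network including differential-hub comparison between
    two conditioned networks and first-neighbor expansion, and
    semiquantitative scoring of tandem affinity purification mass
    spectrometry (TAP-MS) tables into molecular-weight-normalized
    abundance and bait-versus-control specificity. A synthetic-data
    module generates expression studies, scale-free interaction
    networks, TAP intensity tables and family annotations with known
    planted structure so that every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
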