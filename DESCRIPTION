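Package: tumormicro
Title: Quantify and Analyze Exogenous Microbial Reads in Tumor RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of taxonomic classifier output from bulk
    tumor RNA sequencing. Parses Kraken2/Bracken reports into taxon count
    tables, removes likely contaminants in four modular phases (microbial
    load outliers, small sequencing batches, a frequency-based statistical
    test against input RNA concentration, and curated deny/spare lists),
    normalizes counts by log-CPM precision weighting with supervised removal
    of technical covariates, builds rarefied prevalence tables, associates
    taxa with overall survival and clinical covariates with a two-cohort
    concordance intersection, and constructs bipartite microbe-gene
    correlation networks with centrality and preranked pathway enrichment.
    Ships a synthetic-cohort generator with planted contamination, batch,
    survival, and correlation structure so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    survival,
    igraph,
    vegan,
    fgsea,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
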