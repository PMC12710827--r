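Package: gemsig
Title: Mapping Metabolite Signatures to Enzyme-Coding Genes via
    Genome-Scale Metabolic Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Connects metabolomics to gene-centric enrichment analysis by
    exploiting the gene-reaction-metabolite structure of genome-scale
    metabolic models (GEMs). Metabolite signatures are resolved against a
    GEM (SBML Level 3 with the fbc extension, or a simple JSON/TSV toy
    dialect), mapped to enzyme-coding genes under non-directional or
    directional stoichiometric rules, and each mapped gene is scored for
    signature specificity with an upper-tail hypergeometric probability.
    Sigmoid-transformed specificity scores serve as weights in a weighted
    hypergeometric over-representation analysis against GMT gene-set
    collections. The package also provides the paired-omics concordance
    statistics used to benchmark such mappings (restricted-background
    overlap tests, Kolmogorov-Smirnov p-value uniformity tests), a seeded
    generator of toy metabolic networks with planted signatures for
    validation, and machine-readable Sankey export for three-layer
    metabolite/metabolite-set/gene-set summaries.
License: GPL-3
Encoding: UTF-8
Depends:
    R (>= 4.2.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, Pathways, GeneSetEnrichment, Network, Software
RoxygenNote: 7.3.3
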