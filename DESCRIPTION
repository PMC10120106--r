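Package: endopan
Title: Metapangenome and Phylosymbiosis Analysis of Plant Endosphere Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing shotgun metagenomes of plant endosphere
    microbiomes from taxonomically binned scaffolds and ortholog gene
    clusters. Implements best-hit taxonomic binning of scaffolds from
    tabular aligner output, read-based taxon abundance profiles with
    median normalization and coverage-ordered scaffold subsampling,
    alpha and beta diversity statistics (Shannon, Simpson, Chao1, ACE,
    rarefaction, Bray-Curtis, PCoA, NMDS, PERMANOVA, Welch and ANOVA
    group tests), core/shell/cloud partitioning of taxa and gene
    clusters with Venn region counts and gene-name consolidation, Gene
    Ontology term enrichment with true-path propagation and elim-style
    graph decorrelation, and a screen of per-cluster gene trees for
    topological concordance with a host phylogeny. A synthetic-data
    module generates every pipeline input with known ground truth so
    all stages are testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
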