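Package: picoevo
Title: Comparative Genomics of Gene Content Evolution in Marine Picocyanobacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse long-term genome diversification in closely
    related bacterial genomes, built around the strains-by-gene-family
    phyletic pattern. Implements core/pan-genome classification and
    rarefaction with exponential core-size asymptote fitting, maximum
    likelihood ancestral presence/absence reconstruction under a two-state
    gain/loss Markov model with discrete-gamma rate variation, per-branch
    gain and loss event counting, time calibration and per-million-year
    rate regressions, sliding-window genomic-island detection with
    island-sharing networks and modularity modules, gene-content versus
    core-protein tree comparison (neighbour joining, branch-length ratio
    tests), screens for clade-specific amino-acid variants and node-fixed
    genes, and sequence relatedness statistics (fragment-based ANI,
    reciprocal-best-hit AAI, GC3). A fully parameterised synthetic-data
    generator emits genomes, trees, phyletic patterns and alignments with
    machine-readable ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    ape,
    phangorn,
    vegan,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
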