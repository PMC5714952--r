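Package: mitocomp
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects: parsing annotated
    circular mitochondrial genomes from GenBank flat files, base composition
    and AT/GC strand-skew statistics by region, codon usage and relative
    synonymous codon usage (RSCU) with truncated-stop handling, gene-order
    and gene-junction (overlap/spacer) census, control-region location,
    tRNA base-pair classification from dot-bracket structures, pairwise
    divergence with synonymous/replacement site classification, sliding-window
    nucleotide diversity (Pi), and phylogenetic supermatrix preparation
    (concatenation with codon-position partitions, Degen recoding, an
    entropy-based substitution-saturation index, PHYLIP/NEXUS/RAxML exports).
    Includes a seeded synthetic-mitogenome generator and sequence evolver so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
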