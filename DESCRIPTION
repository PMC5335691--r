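Package: mitocomp
Title: Comparative Mitogenomics of Gene Order Rearrangements and Codon Usage
Version: 0.1.0
Authors@R:
    person("Mito", "Comp", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes, built around the 37-gene circular mitogenome and the pancrustacean
    ground pattern. Reads and writes GenBank flat files, screens annotations
    for common database defects (missing or duplicated genes, inverted or
    absent coordinates), extracts strand-signed circular gene orders,
    classifies rearrangement events (tRNA translocations, inversions, block
    inversions, duplications, losses) against a reference arrangement, groups
    identical arrangements into named patterns and tests their consistency
    with a phylogeny by Fitch parsimony. Codon usage of the 13 protein-coding
    genes is analysed under the invertebrate mitochondrial genetic code:
    codon counts, relative synonymous codon usage (RSCU), per-amino-acid
    chi-square comparisons among taxonomic groups, and classical
    multidimensional scaling of RSCU profiles. A seeded synthetic-data
    generator produces fully annotated mitogenome fixtures so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
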