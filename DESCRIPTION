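Package: endophylo
Title: Homeolog Copy Recovery and Mitochondrial Phylogenomics for
    Heteroploid Fungal Endophytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recovers the multiple homeologous nuclear gene copies carried by
    hybrid (heteroploid) asexual fungal endophytes from short paired-end
    reads, by reference-guided read recruitment, coordinate padding and
    variant-linkage phasing; assembles the high-copy mitochondrial genome by
    de Bruijn contig assembly with depth-based organelle classification,
    reference-guided ordering and protein-gene annotation; predicts gene-copy
    functionality by translation; and reconstructs neighbour-joining and
    Fitch-parsimony phylogenies with bootstrap consensus for individual gene
    copies, concatenated markers and mitochondrial gene complements. Includes
    a fully ground-truthed simulator of interspecific hybrid genomes and
    paired-end sequencing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    data.table,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
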