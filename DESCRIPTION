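Package: haploweb
Title: Haplotype Webs, Fields for Recombination, and Robertsonian
    Karyotype Models for Hybrid-Zone Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multilocus species delimitation in diploid
    organisms sequenced by direct (Sanger) sequencing.  Reads aligned
    multi-FASTA with IUPAC ambiguity codes marking heterozygous sites,
    phases heterozygous genotypes against the pool of observed
    homozygotes, builds minimum-spanning haplotype networks augmented
    with heterozygote co-occurrence arcs ("haplowebs"), delimits fields
    for recombination (FFRs), combines loci into a conspecificity
    matrix, and classifies specimens as pure, hybrid, or introgressed,
    including mito-nuclear discordance reporting.  A Robertsonian
    fusion karyotype model computes diploid numbers and predicts F1
    hybrid karyotypes, and a synthetic-data generator with truth
    tables makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
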