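Package: pennid
Title: Molecular Identification of Fountain Grass Species and Hybrid Cultivars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification pipeline for the ornamental fountain grasses
    Pennisetum setaceum and Pennisetum advena and their hybrid cultivars from
    DNA barcode data. Builds quality-trimmed IUPAC consensus sequences from
    bidirectional Sanger reads, maps amplicon short reads to locus references
    (rbcL, trnH-psbA, ITS), calls variants from pileups, deconvolves
    intra-individual ITS variant mixtures into proportion estimates, assigns
    chloroplast haplotypes at diagnostic sites, and integrates all loci into a
    per-specimen species / hybrid / maternal-lineage verdict with an optional
    morphological range check. Includes a seeded synthetic-data generator that
    emulates the divergence structure of the two species (2 and 4 diagnostic
    substitutions on the chloroplast loci, ~90% ITS identity, intra-specific
    ITS variants, and a single-indel chloroplast mixture).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
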