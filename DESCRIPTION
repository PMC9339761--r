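Package: haploshare
Title: Chloroplast Haplotype Sharing Analysis for Co-Distributed Plant Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of non-recombining organellar
    (chloroplast) sequence data from multiple co-distributed species: character
    coding of aligned non-coding loci (substitutions, simple gap coding of
    indels, inversion recoding, masking of mononucleotide repeats), haplotype
    collapsing, median-joining haplotype networks, population diversity and
    GST/NST differentiation with permutation tests, hierarchical analysis of
    molecular variance (AMOVA), individual-level spatial autocorrelograms, and
    a distance-stratified test of interspecific gene identity that separates
    shared ancestral polymorphism (geographically random haplotype sharing)
    from introgression (local sharing between nearby heterospecific
    populations). Includes a synthetic-data generator that emulates the
    multi-refugium, three-lineage structure the analysis assumes, so every
    stage can be exercised against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
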