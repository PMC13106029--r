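Package: ckRNAi
Title: Cross-Kingdom Small RNA Discovery and Target Analysis for
    Arbuscular Mycorrhizal Symbiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cross-kingdom small RNAs delivered by an
    arbuscular mycorrhizal fungus into Argonaute complexes of its host plant.
    Starting from AGO co-immunoprecipitation small RNA libraries of mock and
    fungus-colonized roots, reads are adapter-clipped, collapsed, classified
    by subtractive perfect-match mapping against host and fungal genomes,
    profiled by size and 5'-terminal nucleotide, assigned to genomic feature
    classes, and filtered to fungus-exclusive 21-24 nt candidates exceeding
    25 reads per million of fungus-mapped reads in every colonized library
    while absent from mock libraries. Host transcript targets are predicted
    with a plant-miRNA-style duplex penalty score and a hybridization
    free-energy ratio, cleavability is called from Watson-Crick pairing at
    sRNA positions 10-11, and short tandem target mimic (STTM) decoys with
    scrambled controls are designed. Downstream readouts include Trouvelot
    mycorrhizal colonization indices and delta-delta-Ct expression fold
    changes. A synthetic-data generator with a machine-readable ground-truth
    manifest makes the entire pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
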