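Package: cbcscope
Title: Structure-Aware Comparison of rDNA Sequences for Algal Taxonomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the structure-aware comparison of ribosomal DNA
    used in green-algal taxonomy: excision of group I introns by
    insertion-block detection against intron-free references,
    template-based transfer of SSU rRNA secondary structure through
    pairwise alignments, classification of variable paired sites as
    compensatory base changes (CBCs), hemi-CBCs or uncoupled
    substitutions, gap-aware p-distances for ITS1/ITS2 comparisons,
    verification of canonical ITS2 structural motifs, and mapping of
    (non-homoplasious) synapomorphies onto clades of a supplied
    phylogeny. A fully deterministic synthetic-data generator plants
    changes of every class with known ground truth so each analysis
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
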