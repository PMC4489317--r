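Package: zgene
Title: Z-Curve Gene Finding and Essential-Gene Scoring for Prokaryotic
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ab initio identification of protein-coding genes in bacterial
    and archaeal genomes using the Z-curve representation of phase-specific
    nucleotide, dinucleotide, trinucleotide and tetranucleotide frequencies
    (a 765-variable encoding, with the legacy 33-variable encoding retained).
    Candidate open reading frames are enumerated in all six frames (with
    circular-chromosome wrap handling), encoded, and classified by a
    genome-specific linear max-margin model trained by self-training
    (long-ORF seeds against shuffled and shadow negatives); translation
    starts are adjusted with a Shine-Dalgarno aware relocator. Includes a
    consensus combiner for merging two prediction sets by 3'-terminus
    identity with a pluggable homology-confirmation hook, a distance-weighted
    ortholog-evidence scorer for gene essentiality, the standard evaluation
    statistics for both tasks (sensitivity, precision, accuracy, additional
    positive rate; overall accuracy, specificity), and a synthetic-genome
    generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
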