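Package: peakperm
Title: Width-Matched Permutation Tests for Genomic Interval
    Colocalization and Enhancer Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how often a set of ChIP-seq binding sites
    overlaps histone-mark regions and assesses significance with a
    width-matched Monte-Carlo permutation null: random interval sets
    preserving the count and width multiset of the observed set are
    placed across the genome and the overlap statistic is recomputed
    for each. Also classifies binding sites into enhancer chromatin
    states from H3K4me1/H3K27ac/H3K4me3 overlap, annotates distance to
    the nearest transcription start site, selects putative distal
    enhancer loci, ranks factor panels by mark-overlap fraction,
    filters MACS-style peak tables, and generates synthetic genomes
    with exactly planted overlap fractions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
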