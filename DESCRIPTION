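Package: composcan
Title: Composite OCT4-SOX2 Motif Scanning in ChIP-seq Peak Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies degenerate composite transcription-factor binding
    words (Hoxb1-like, Utf1-like and Fgf4-like OCT4-SOX2 elements) in
    100-bp windows centered on ChIP-seq peak summits, builds positional
    distributions against GC-matched background sequences, links
    motif-bearing peaks to genes by summit-to-TSS distance, and classifies
    fold-change expression differences of motif-class gene sets between
    rescued embryonic stem cell lines. Ships a seeded synthetic-data
    generator (genomes, peak sets with planted motifs, TSS tables,
    expression matrices with planted effects) with ground-truth tables so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
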