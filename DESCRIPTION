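Package: riboterm
Title: Translation Termination Analysis from Ribosome Profiling Density
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing translation termination and recoding in
    bacterial ribosome profiling data. Converts aligned ribosome footprints
    to per-nucleotide density tracks by centre or 3'-end mapping, builds
    stop-codon-aligned metagene profiles with upstream-window normalisation,
    computes the relative post-ORF ribosome occupancy (RPOR) statistic and
    compares its distributions with the Kolmogorov-Smirnov test, detects
    candidate stop-codon readthrough and frameshifting events from density
    drops at post-ORF stop codons, estimates programmed frameshifting from
    two-ORF loci, and tests stop-codon enrichment among recoding calls.
    Includes a ground-truth simulator of genomes, annotations and density
    tracks with known expression, stop-pause, readthrough and frameshift
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
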