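Package: cqscan
Title: Chromosome-Quotient Sex-Chromosome Classification and Repeat
    Divergence Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative X- and Y-linked contigs in fragmented
    genome assemblies of species with heteromorphic sex chromosomes using
    the chromosome quotient (CQ): the ratio of female to male read
    alignment counts under a stringent whole-read, zero-mismatch matching
    criterion. Also computes Kimura 2-parameter divergence between
    transposable-element insertions and their consensus (ancestral)
    sequences, builds binned repeat accumulation landscapes, and reports
    standard assembly statistics (N50, AT content, N density). Includes a
    sexed-genome simulator (autosomal, X- and Y-linked contigs; female and
    male read pools at configurable depth and error rate; planted TE
    copies mutated to target divergences) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
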