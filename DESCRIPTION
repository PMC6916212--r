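Package: splicesim
Title: Splicing-Aware Simulation of Gene and Transcript Sequence Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the evolution of a gene family along a rooted guide
    tree, jointly modelling the exon-intron structure of genes (exon loss,
    gain and tandem duplication), the set of alternative transcripts
    produced from each gene (transcript loss and creation by random isoform
    selection or by one of the five elementary alternative-splicing event
    types), and sequence evolution (empirical codon Markov chains, codon
    substitution and indel events in exons, nucleotide-level events in
    introns). Every simulated nucleotide is tracked by descent, so the true
    multiple alignments of genes and cDNAs, the full event history, and the
    splicing-ortholog groups of transcripts are emitted as ground truth for
    benchmarking spliced-sequence analysis methods. Also provides the
    evaluation metrics used with such benchmarks: alignment
    precision/recall/F-score against a reference alignment and the Rand
    index of a clustering against reference groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
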