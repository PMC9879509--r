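Package: tandemscope
Title: Detection and Characterization of Perfect Tandem Repeats in Giant
    Linear Genomes
Version: 0.1.0
Authors@R: person("tandemscope", "developers", role = c("aut", "cre"),
    email = "tandemscope@example.org")
Description: Detects perfect (mismatch-free) nucleotide and amino-acid
    tandem repeats in linear genomes and characterizes them: flanking
    partial repeats and phase alternatives, genic/intergenic context and
    the divisible-by-three rule, GC skew and replichore prediction,
    windowed nucleotide-composition contrasts (Kruskal-Wallis with
    Benjamini-Yekutieli FDR), codon usage inside repeat regions,
    amino-acid repeat clustering with rule-based naming, spanning-read
    unit-number variation, and per-genome summary reports. Includes a
    synthetic genome generator with machine-readable planted truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
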