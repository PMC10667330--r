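Package: chromoforge
Title: Design, Build Planning and Debugging Toolkit for Synthetic Yeast Chromosomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational machinery for Sc2.0-style synthetic chromosome
    engineering in Saccharomyces cerevisiae. Applies rule-driven design
    edits (loxPsym insertion after non-essential stop codons, intron
    removal, TAG-to-TAA stop swaps, synonymous PCR-tag recoding, telomere
    standardization, tRNA/transposon removal) to a native chromosome while
    maintaining a verifiable, invertible edit ledger; partitions the
    designed sequence into SwapIn chunks and megachunks with restriction
    junctions and alternating auxotrophic markers; calls PCR-tag genotypes
    and megachunk acceptance from qPCR plates and computes
    efficiency-corrected relative expression; localizes growth-defect loci
    from pooled fast/slow sequencing coverage, estimates copy number from
    relative read depth, classifies design-versus-observed sequence
    discrepancies and plans proximity-bundled repairs; designs relocated
    tRNA arrays with heterologous flanks matched by anticodon; and
    simulates Cre-loxPsym SCRaMbLE on haploid to tetraploid
    synthetic/wild-type hybrid genomes, scoring viability through
    essential-segment retention and classifying ploidy from
    propidium-iodide histograms. All inputs can be generated by seeded
    fixture simulators for fully synthetic end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
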