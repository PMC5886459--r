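Package: poolphase
Title: Haplotype Reconstruction from Pooled Amplicons with Known Mixing Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the individual haplotype sequences present in a pooled
    amplicon sequencing sample in which each haplotype was mixed at a known,
    distinct concentration (for example 1:2:5). Mapped reads are converted into a
    gap-consistent multiple alignment, windowed read-coverage proportions are
    modelled with a Dirichlet-multinomial hidden Markov model, and the most
    likely assignment of window sub-sequences to haplotypes is decoded with a
    bidirectional Viterbi algorithm. Includes the companion computations: pool
    design proportion algebra, coverage sub-sampling arithmetic, a reconstruction
    error metric, quality-weighted consensus calling, a paired-read pool
    simulator, and a pooled-versus-barcoded sequencing cost model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
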