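Package: scramblesv
Title: Simulation and Split-Read Detection of SCRaMbLE Genome Rearrangements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale implementation of the computational pipeline used to
    evolve and characterize geraniol-producing synthetic yeast strains. Models
    synthetic chromosomes partitioned by 34-bp palindromic loxPsym sites,
    simulates Cre-mediated SCRaMbLE rearrangements (deletion, inversion,
    tandem duplication) with exact ground truth, generates paired-end reads
    with Phred-scored substitution errors, and recovers the events with a
    quality filter, an exact seed-and-extend ungapped read mapper, per-segment
    depth profiling, and a loxPsym split-read junction caller that types
    events from breakpoint orientation and coverage depth. Also provides the
    companion enzyme-engineering utilities: BLAST-style homolog-hit filtering,
    six-frame longest-ORF extraction, N-terminal chimera construction,
    RR-motif truncation, p-distance neighbor-joining phylogeny, and microplate
    OD340 dehydrogenase screening statistics (calibration, hit calling,
    specific activity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
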