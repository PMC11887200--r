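Package: TargetPolish
Title: Targeted Long-Read Polishing of Draft Genome Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Targeted base-error correction for draft genome assemblies.
    Soft-masked (lowercase) regions of a draft assembly, or regions given in
    a BED file, are excised together with short flanking context, polished
    with a per-target Bloom-filter k-mer edit engine driven by long reads
    assigned to each target via PAF coordinate liftover, and spliced back
    into the assembly. Includes case-preserving FASTA/FASTQ/BED/PAF readers
    and writers, a deterministic synthetic-fixture generator (truth genome,
    error-injected soft-masked draft, simulated long reads, truth PAF) and a
    truth-aware banded-alignment evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
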