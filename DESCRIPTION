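Package: svstream
Title: Real-Time Batch-Incremental Structural Variant Detection from Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A streaming framework for structural variant (SV) discovery from
    long-read alignment batches produced while a sequencer is still running.
    Each batch contributes read-level SV signatures (intra-alignment evidence
    from CIGAR insertions and deletions, inter-alignment evidence from split
    reads) to a cumulative store; clustering and binomial genotyping of the
    store yield an interim VCF after every cycle, with a support-read
    threshold that adapts to the accumulated sequencing depth. A detection-rate
    feedback statistic against a frequency-filtered population truth set
    recommends early sequencing termination, and atomic checkpoints allow
    fault recovery with a final callset identical to an uninterrupted run.
    Includes a synthetic fixture generator that emulates batch-wise sequencer
    output with implanted SVs and a matching truth VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicAlignments,
    IRanges,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
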