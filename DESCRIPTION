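Package: abescan
Title: Genome-Wide Detection and Classification of Adenosine Base Editor
    Off-Target Edits from Enriched ssDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and classifies genome-wide dA-to-dI off-target edits
    produced by adenosine base editors (ABEs) from endonuclease-V-enriched
    single-stranded DNA sequencing reads. Candidate sites are called from the
    truncated-read signature (the edited adenosine read as G at the second
    aligned base of a read) through a seven-rule filter cascade, scored by the
    fraction of truncated mutant reads, and classified as Cas9-dependent or
    Cas9-independent by a modified semiglobal affine-gap alignment of the
    sgRNA protospacer-plus-PAM against the surrounding genome. Additional
    components quantify editing rates from UMI-tagged amplicon reads with
    consensus deduplication and background subtraction, fit ridge regressions
    relating binding-site mismatch/gap/PAM features to out-of-protospacer and
    target-strand editing, and simulate aligned reads with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
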