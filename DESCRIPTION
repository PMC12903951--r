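Package: nanosift
Title: Self-Optimizing Adapter/Primer Detection and Preprocessing for
    Nanopore cDNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocesses Oxford Nanopore cDNA sequencing reads by locating
    adapter/primer (AP) sequences with edit-distance infix alignment and
    learning, per dataset, the similarity, location and AP-substring-length
    cutoffs that best separate genuine end-of-read AP hits from random
    alignments. Each read is aligned twice per AP (the best hit, then the
    best hit on the remainder of the read) so that true and random alignment
    score distributions can be sampled from the data itself; cutoffs are then
    chosen by maximizing an F-beta objective over a grid. Reads are
    classified as full-length, truncated or chimeric, reoriented to the sense
    strand, trimmed of APs and the adjacent polyA tail, and quality-filtered
    as the final step. A ground-truthed read simulator (composition mixtures,
    substitution/insertion/deletion errors, elevated terminal error rates)
    and a precision/recall benchmark harness are included, plus a
    command-line interface and a machine-readable tuning report with a static
    HTML rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    graphics,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
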