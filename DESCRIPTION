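Package: armshrma
Title: Allele-Specific PCR with High-Resolution Melting Analysis for KRAS
    Codon 12 Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes high-resolution melting (HRM) curves from allele-specific
    (ARMS) PCR assays targeting the KRAS G12V and G12D hotspot mutations.
    Raw per-well fluorescence traces are smoothed, transformed to negative
    derivative (-dF/dT) and wild-type-reference difference plots, and scored
    for the presence of the target allele by normalising the melting-peak
    intensity against matched mutant and wild-type cell-line controls with a
    0.5 decision threshold.  Multi-method genotype call tables (ARMS-HRMA,
    Sanger sequencing, droplet digital PCR) are compared through per-assay
    call counts, pairwise concordance with explicit missing-data handling,
    and Mann-Whitney rank tests.  A melt-curve simulator with allele-specific
    amplification efficiencies and two-state melting transitions generates
    full cohorts so every stage of the pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
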