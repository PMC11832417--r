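Package: chromflux
Title: Quantitative DNA Accessibility Analysis by Methyltransferase Footprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of genome-wide DNA accessibility measured by inducible
    DNA methyltransferase probing in budding yeast. Computes per-site
    fraction-cut (fcut) from paired-end fragment ends with terminal-base
    correction and neighbor-proximity rules, estimates limit-digest plateaus
    and apparent first-order methylation rate constants by genomic region,
    builds dyad-aligned nucleosome-phasing profiles with shift and disorder
    metrics, and aggregates Nanopolish-style long-read CpG methylation calls.
    Includes a ground-truthed synthetic chromatin and methylation simulator
    (static nuclei and dynamic in vivo modes, DpnI cutting, sonication,
    fragment recovery loss and terminal-base removal) so every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
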