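Package: optoxr
Title: Design of Light-Activatable Receptor Chimeras (opto-XRs)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing opto-XR chimeric receptors: a
    channelrhodopsin-like light-sensing backbone whose intracellular
    loops and C-terminus are replaced by those of a target G
    protein-coupled receptor. Calls seven-transmembrane (7TM) topology
    from Kyte-Doolittle hydropathy with consensus refinement over
    aligned homolog families, splices the intracellular parts of the
    target into the backbone, compiles a codon-optimized,
    restriction-audited, reporter-fused expression cassette, designs
    junction-spanning qPCR primer pairs verified by in-silico PCR, and
    computes relative expression by the 2^-ddCt method. Includes seeded
    synthetic-data generators so the whole workflow is testable without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
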