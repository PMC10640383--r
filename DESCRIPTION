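Package: gevescan
Title: Detection and Characterization of Giant Endogenous Viral Elements
Version: 0.1.0
Authors@R: person("GEVE", "Maintainers", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools to detect and characterize giant endogenous viral
    elements (GEVEs) on eukaryotic chromosomes. Combines per-ORF viral and
    cellular homology bitscores into a rolling-window score track and calls
    contiguous viral regions; validates candidate insertions with
    junction-spanning long reads, coverage uniformity, Hi-C contact
    enrichment and cross-strain comparison; annotates gene decay
    (pseudogenes, intron candidates, intergenic gene traces) via
    STOP-to-STOP ORF inventories and translated homology search; and ships
    a fully ground-truthed synthetic endogenization generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
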