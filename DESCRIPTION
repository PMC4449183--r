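Package: gh20arch
Title: Domain Architecture and Active-Site Completion Analysis of GH20 Hexosaminidases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural survey tools for family GH20 beta-N-acetylhexosaminidases
    and lacto-N-biosidases. Integrates per-database domain annotations into a
    consensus architecture and classifies enzymes into Model A (GH20b-GH20-alpha)
    or Model B (catalytic GH20 domain only); assigns secondary structure from
    backbone hydrogen bonds, detects the catalytic (beta/alpha)8 barrel and its
    numbered loops; anchors the conserved subsite -1 arginine/aspartate pair and
    locates the remote element (long loop 2, an accompanying domain, or the dimer
    partner) that completes the substrate-binding cavity; and provides sequence
    utilities for truncation-construct design, including theoretical molecular
    masses of His6-tagged expression constructs. Ships a synthetic-structure
    generator (ideal helices, beta hairpins, mini barrels, planted contact pairs)
    so the whole pipeline is testable without database downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
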