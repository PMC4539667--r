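Package: gcscreen
Title: Compositional Outlier Screening of GC-Rich Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-gene GC content and G/C-stretch statistics for coding
    sequences, an empirical background distribution with percentile-based
    outlier screening, permutation two-sample comparison of compositional
    metrics between gene groups, G-quadruplex motif scanning, and a seeded
    two-state Markov simulator of CDS-like sequences together with a
    GC-biased sequencing-coverage model. Built to study why GC-rich avian
    genes are systematically under-represented in genome assemblies and
    sequence databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    tibble,
    dplyr,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
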