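Package: phagerank
Title: Enrichment Analysis of Phage Display Selections from NGS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis engine for next-generation sequencing of phage display
    and mirror-image phage display selections. Extracts a user-defined
    randomized region from FASTQ reads using a pair of constant framing
    anchor sequences, checks reading-frame integrity, translates inserts
    under four strand/orientation modes, tallies sequences at the DNA level
    with parts-per-million normalization per selection round, and ranks
    candidate binders by control-aware enrichment and empty scores. Results
    are persisted in a single-file SQLite database with one table per
    selection round plus an evaluation table. A synthetic-campaign simulator
    generates FASTQ selections with planted binders, anchor point mutations
    and frame-shifting deletions together with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
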