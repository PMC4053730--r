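Package: taxvote
Title: Consensus Taxonomic Classification of Amplicon Sequences by
    Bottom-Up Voting on BLAST Hits
Version: 1.0.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Assigns taxonomy to 18S rRNA and ITS amplicon sequences by
    consensus voting over tabular BLAST output. Hits are filtered for
    query coverage and percent identity, then vote bottom-up through the
    eight standardized ranks (domain to species) against a local NCBI
    taxdump-style taxonomy, with rank-specific identity and majority
    thresholds and exclusion of generic or partial database annotations
    (e.g. "uncultured" entries). Emits QIIME-compatible standardized and
    full-lineage taxonomy tables plus a per-rank voting log. Also
    provides an in silico amplicon community simulator (per-base
    substitution errors, exponential 3' truncation, emulated BLAST hit
    tables) and an IUPAC-degeneracy-aware semi-global edit-distance
    profiler for degenerate primers against clade-grouped targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
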