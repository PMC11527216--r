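Package: refcov
Title: Audit Reference-Sequence Coverage for DNA Barcoding Loci
Version: 1.0.0
Authors@R:
    person("Robin", "Holm", email = "rholm@example.org", role = c("aut", "cre"))
Description: Audits the availability of DNA-barcode reference sequences per
    organism and per barcoding locus across pluggable record sources: live
    NCBI Nucleotide (Entrez E-utilities), the BOLD public API, local
    CRUX-style per-barcode reference databases, and offline tab-separated
    snapshots. Builds organism-by-locus coverage matrices with
    taxonomy-rank fallback (genus, family, order) for species without
    records, per-barcode summary tables, country-of-origin tallies,
    cross-database deduplication of BOLD records mirrored in GenBank,
    deterministic Entrez search-statement export, and per-barcode FASTA
    bundles for downstream reference-database construction. Ships a
    seeded synthetic snapshot generator with planted coverage structure
    so the full workflow is testable offline, and a command-line
    interface (audit, fetch, synth, dedupe).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
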