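---
title: "Auditing reference-sequence coverage for DNA barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing reference-sequence coverage for DNA barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcov)
```

## The model

An eDNA assay — whether a metabarcoding survey or a species-specific
qPCR test — can only detect what its reference database can name.
`refcov` treats the preparatory question "which of my organisms have
reference sequences at which barcode loci?" as a counting problem over
a *record source*: any database that can answer
(organism, barcode group, filters) queries with a count and a record
table. The match predicate is deliberately plain keyword search:

- organism: exact scientific-name equality, case-insensitive, after
  whitespace normalization. No fuzzy matching at the source layer —
  corrections are a separate, logged step (below).
- marker: the record's raw marker label must normalize into the
  queried *barcode group*, a canonical locus name plus its synonym
  spellings (`CO1` ~ `COI` ~ `COX1` ~ "cytochrome c oxidase subunit
  I"). Matching is case-insensitive *exact* comparison per synonym,
  never substring matching, which would silently swallow labels like
  `CO12`.
- filters: inclusive length bounds and a country-of-origin set.

Keyword search inherits the databases' metadata quality: a mislabeled
record is counted as labeled. Records therefore carry their metadata
verbatim — the package never corrects a field silently — and
`validate_record()` reports inconsistencies instead of fixing them.

### Coverage matrix and summary

The coverage matrix is the central artifact: rows are the user's
organisms in input order, columns are barcode groups, cells are counts.
Three cell states are distinguished: a positive count, a true zero (a
reference gap), and `NA` (the search itself failed —
`SOURCE_UNAVAILABLE` is a classed condition, never conflated with
zero; conflating them would corrupt gap analysis).

The per-barcode summary reports, for each barcode `b`: sequences found
`n_b`, percentage share `100·n_b/Σn` (computed from raw counts, then
half-up rounded to one decimal — identities are asserted before
rounding), organisms covered, organisms missing. Covered + missing
always equals the number of input organisms. The summary uses
species-rank cells only: fallback counts (next section) live at other
taxonomic ranks, and mixing ranks in one total would double-count.

### Name corrections: append, never replace

User-supplied names pass through a pluggable resolver
(`table_resolver()` is the offline default, driven by a
`wrong_name,correct_name` CSV). A correction is *appended* to the
organism's name list and logged; the original is never edited or
removed, so a bad correction cannot silently hijack a query. Counts
pool over all resolved names into one row per input organism. Homonym
disambiguation is out of scope (a documented limitation of
keyword-based search): a name shared across kingdoms will count both.

### Rank fallback

When a species-rank cell is zero, the organism's lineage is looked up
in the taxonomy backbone and its genus, family and order are queried
in that fixed order with subtree semantics (all records whose lineage
passes through the ancestor). Design choices made here, where behavior
was genuinely open:

- *All three ancestor ranks are reported*, not stop-at-first-nonzero:
  the extra counts cost one query each and gap analysis wants them.
  Counts are monotone non-decreasing up the ladder on
  subtree-consistent sources, which the tests assert.
- *Fallback is gated strictly on a zero species count* — never issued
  when the species has records (asserted on the query log).
- *The backbone wins over the binomial.* A moved species (its backbone
  genus differs from the first word of its binomial, as with a
  *Lithobates* reassigned to *Aquarana*) walks the backbone's genus,
  and the divergence is raised as a `taxonomy_drift` warning rather
  than silently picking either side.
- *Unregistered names end the walk.* A species absent from the
  backbone keeps its all-zero row, is flagged `UNREGISTERED`, and no
  ancestor query is attempted — without a backbone entry there is no
  tree to climb. This also means a genuinely new species and a
  misspelled one look identical; the correction table is the remedy.

### Cross-database deduplication

BOLD records often mirror a GenBank entry and carry its accession as a
cross-reference. `dedupe_cross_db()` removes BOLD records whose
cross-reference — version suffix stripped, since BOLD and NCBI
disagree on version notation — appears in the NCBI accession set, so a
combined NCBI+BOLD download contains each sequence once. Records
without a cross-reference are always kept: with no key there is no
evidence of duplication, and dropping them would undercount.

## Record sources

Four implementations of one contract (`count_matches`,
`fetch_records`, `count_subtree`, capabilities):

- **snapshot**: an offline TSV of records plus a backbone TSV;
  the reference implementation and the test substrate.
- **CRUX directory**: one FASTA + taxonomy-TSV pair per barcode
  (`accession<TAB>superkingdom;...;species`). The species field is the
  record's organism; the subdatabase name is its marker. Malformed
  entries (wrong rank-field count, FASTA id absent from the taxonomy
  table) are skipped and itemized — loading continues, because a
  curated database with three bad lines is still a database. An audit
  against a CRUX source always reports *every* subdatabase present,
  zeros included: the user does not choose barcodes there.
- **NCBI Nucleotide**: E-utilities, two-phase search-then-fetch
  (esearch with `retmax` paging, efetch in batches of at most 200
  ids), 3 requests/s without an API key and 10/s with one, exponential
  backoff with 5 attempts, failures surfacing as `SOURCE_UNAVAILABLE`.
  Ancestor queries are issued as `[ORGN]` terms, which Entrez expands
  over the subtree. Fielded mode searches `[GENE]`/`[ORGN]`;
  `all_fields` mode exists because gene metadata is often incomplete.
- **BOLD**: the public combined specimen+sequence API, one taxon per
  request, subtree semantics delegated to the service.

Both live sources take an injectable transport function
(URL → response text) and an optional on-disk response cache keyed by
request URL: iterative re-searching with adjusted parameters is the
dominant use pattern, and it should not re-hit the endpoints. The test
suite exercises the live code paths exclusively through canned-response
transports; no test touches a network.

### Query statements

Entrez terms are serialized deterministically — synonyms OR-ed inside
one statement in declared group order, organism quoted in `[ORGN]`,
optional `("min"[SLEN] : "max"[SLEN])` range (a single bound fills the
other side with 1 or 99999999; NCBI has no one-sided range). OR-ing
synonyms into one statement (rather than one query per spelling) costs
one round-trip per organism-barcode pair and gives exactly the union
semantics the coverage matrix cell wants. Embedded double quotes in
names are rejected, not escaped: NCBI term syntax has no portable
escape, and a loud failure beats a silently corrupted query. Every
statement is exportable, so results can be validated by pasting into
the database's own interface.

## The synthetic generator

`coverage_plan()` states a world: organisms with lineages, barcodes, a
planted count per pair, a BOLD/NCBI overlap size, a country pool with
a missing-metadata probability (0.2 by default — public records quite
often lack a country), a length range (400–700 nt by default, the span
of typical barcode amplicons), and a seed. `generate_snapshot()`
realizes exactly that world: cell-for-cell counts, marker labels
cycling through each group's synonym spellings so normalization is
exercised, uniform-random A/C/G/T sequences (the audited predicate
never reads sequence content, so compositional realism would buy
nothing), unregistered organisms omitted from the backbone. The plan
is the oracle: recovery of `counts` by `build_coverage_matrix()` is
the package's first acceptance property.

What the generator deliberately does *not* emulate: real accession
formats (synthetic ids use distinct prefixes to avoid collision),
taxonomic homonyms, metadata errors, API latency or failure patterns
(failure injection lives in the tests), and the live databases'
continuously drifting contents. A green test therefore establishes
that the machinery counts, filters, deduplicates and serializes
correctly — not that any particular live-database number is
reproducible. Published counts against live databases go stale by
design, which is why acceptance here is property-based rather than
pinned to printed totals.

The bundled `demo_plan()` emulates a realistic audit of 11 invasive
California species — CO1 covering five organisms, 16S six,
one species unregistered, one moved genus, congeners planted so
genus-fallback finds hits. Its lineages are *synthetic stand-ins*
shaped like real taxonomy, not authoritative classification.

## Numerical and formatting choices

- Percentages: half-up rounding to one decimal
  (`floor(10x + 0.5)/10`), applied for display only; conservation
  identities are checked on raw counts, and the displayed column sums
  to 100 ± 0.5 whenever the total is positive.
- Length filters are inclusive on both bounds. Records with
  unparseable length metadata are kept while no length filter is
  active and dropped (counted in a report attribute) once one is —
  dropping them silently at all times would hide coverage.
- Country matching is case-insensitive on trimmed names; records with
  no recorded country answer only to the reserved name
  `"Unspecified"`, which makes "show me the un-georeferenced records"
  an ordinary filter.
- Every writer is byte-deterministic: fixed column order, LF endings,
  no timestamps in content (the FASTA-bundle manifest carries the
  timestamp instead). The zip bundle is written by the package itself
  with the STORE method and a fixed 1980-01-01 DOS timestamp because
  external zip tools embed wall-clock time, which would break
  reproducibility; FASTA inside uses 80-column wrapping and one blank
  line between records, which the common alignment suites accept.
- The default barcode-group synonym table is this package's own
  curation (the loci are standard; their spellings in the wild are
  not). Bare "ITS" belongs to neither FITS (fungal) nor PITS (plant):
  assigning it to either would break the disjointness invariant that
  makes marker normalization unambiguous. Users can ship their own
  table via `read_barcode_groups()`.

## Known limitations

Keyword search trusts metadata; homonyms are not disambiguated;
unregistered taxa cannot be walked up the tree; live NCBI fetches tag
records with the queried organism and group (the FASTA payload carries
no structured marker/country fields); and counts from live databases
are snapshots of moving targets — re-running a live audit later is
expected to give different numbers.
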