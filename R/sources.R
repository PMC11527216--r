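# The record-source contract. Four implementations ship with the
# package: offline snapshot, local CRUX directory, live NCBI Nucleotide
# and live BOLD. All expose the same counting/fetching surface so the
# coverage and taxonomy layers are source-agnostic.

#' @name record_source
#' @title The record-source contract
#' @description A record source answers organism x barcode-group queries
#'   with counts ([count_matches()]) and record tables
#'   ([fetch_records()]), and advertises its capabilities: `COUNT`,
#'   `FETCH`, `SUBTREE_QUERY` (counting at an ancestor taxon) and
#'   `COUNTRY_METADATA`. On a static source, `count_matches(q)` always
#'   equals `nrow(fetch_records(q))`. Source failures raise a
#'   `refcov_source_unavailable` condition — never silently a zero
#'   count.
NULL

#' @rdname record_source
#' @param src A record source.
#' @return `source_name()`: a string; `source_capabilities()`: a
#'   character vector of capability names.
#' @export
source_name <- function(src) UseMethod("source_name")

#' @rdname record_source
#' @export
source_capabilities <- function(src) UseMethod("source_capabilities")

#' Count records matching an organism x barcode-group query
#'
#' The match predicate is: organism scientific name equal
#' (case-insensitively, after whitespace normalization — no fuzzy
#' matching at the source layer), marker label normalizing into the
#' barcode group, and all filters passing.
#'
#' @param src A record source supporting `COUNT`.
#' @param organism Scientific name to match exactly.
#' @param group A [barcode_group()].
#' @param filters A [filter_spec()].
#' @return Non-negative integer count. A failed source raises
#'   `refcov_source_unavailable` (distinguished from a true zero).
#' @export
count_matches <- function(src, organism, group, filters = filter_spec()) {
  UseMethod("count_matches")
}

#' Fetch records matching an organism x barcode-group query
#'
#' Same predicate as [count_matches()]. Record order is deterministic:
#' accession-sorted for snapshot/CRUX sources, server order (accession
#' tie-broken) for live sources.
#'
#' @inheritParams count_matches
#' @param want_sequence When `TRUE`, records carry sequence text.
#' @return A record table (see [empty_records()]).
#' @export
fetch_records <- function(src, organism, group, filters = filter_spec(),
                          want_sequence = FALSE) {
  UseMethod("fetch_records")
}

#' Count records beneath an ancestor taxon
#'
#' Subtree semantics: all records whose lineage passes through `taxon`
#' at `rank` count, whatever their species. Snapshot/CRUX sources walk
#' their taxonomy backbone; BOLD delegates to the service; NCBI issues
#' the taxon as an `[ORGN]` term (Entrez expands the subtree).
#'
#' @inheritParams count_matches
#' @param rank Rank of the ancestor (`"genus"`, `"family"`, `"order"`, ...).
#' @param taxon Ancestor taxon name.
#' @return Non-negative integer count.
#' @export
count_subtree <- function(src, rank, taxon, group,
                          filters = filter_spec()) {
  UseMethod("count_subtree")
}

# Shared predicate scan over a record table; the reference semantics
# every source implementation must agree with.
match_records <- function(records, organism, group,
                          filters = filter_spec()) {
  stopifnot(inherits(group, "barcode_group"),
            length(organism) == 1, !is.na(organism))
  if (nrow(records) == 0) return(records)
  org_ok <- !is.na(records$organism) &
    norm_name(records$organism) == norm_name(organism)
  mk_ok <- !is.na(records$marker) &
    norm_name(records$marker) %in% tolower(group$synonyms)
  out <- records[org_ok & mk_ok, , drop = FALSE]
  out <- apply_length_filter(out, filters$min_length, filters$max_length)
  out <- apply_country_filter(out, filters$countries)
  rownames(out) <- NULL
  out
}
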