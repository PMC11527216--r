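# Domain types shared by every module: sequence-record tables, barcode
# groups (a canonical locus plus its synonym marker spellings), lineages,
# filter specifications, organism queries and search statements.

RECORD_COLS <- c("source_db", "accession", "organism", "lineage", "marker",
                 "seq_length", "country", "genbank_xref", "sequence")

SOURCE_DBS <- c("NCBI", "BOLD", "CRUX", "SNAPSHOT")

LINEAGE_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                   "genus", "species")

# IUPAC nucleotide codes (incl. U) plus gap
SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")

#' An empty sequence-record table
#'
#' Sequence records are held as a data.frame with one row per database
#' entry and a fixed column order: `source_db`, `accession`, `organism`,
#' `lineage`, `marker`, `seq_length`, `country`, `genbank_xref`,
#' `sequence`. Missing metadata is `NA`, never an empty string. Metadata
#' is carried verbatim from the source database and never corrected
#' silently.
#'
#' @return A zero-row data.frame with the canonical record columns.
#' @export
empty_records <- function() {
  data.frame(
    source_db = character(0), accession = character(0),
    organism = character(0), lineage = character(0), marker = character(0),
    seq_length = integer(0), country = character(0),
    genbank_xref = character(0), sequence = character(0),
    stringsAsFactors = FALSE
  )
}

#' Coerce a data.frame to the canonical record-table layout
#'
#' @param df A data.frame containing at least `source_db`, `accession`,
#'   `organism` and `marker` columns; missing optional columns are added
#'   as `NA`.
#' @return A record table (see [empty_records()]).
#' @export
as_records <- function(df) {
  if (nrow(df) == 0 && length(setdiff(RECORD_COLS, names(df))) == length(RECORD_COLS)) {
    return(empty_records())
  }
  need <- c("source_db", "accession", "organism", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rc_abort("bad_records", paste0("record table lacks column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  for (col in setdiff(RECORD_COLS, names(df))) {
    df[[col]] <- if (col == "seq_length") NA_integer_ else NA_character_
  }
  df <- df[RECORD_COLS]
  for (col in setdiff(RECORD_COLS, "seq_length")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  df$seq_length <- as.integer(df$seq_length)
  rownames(df) <- NULL
  df
}

#' Construct a single sequence record
#'
#' @param source_db One of `"NCBI"`, `"BOLD"`, `"CRUX"`, `"SNAPSHOT"`.
#' @param accession Unique identifier within `source_db`.
#' @param organism Scientific name as recorded by the source.
#' @param marker Raw marker/gene label as recorded (see
#'   [normalize_marker()]).
#' @param sequence Nucleotide text, or `NA` for a metadata-only record.
#' @param seq_length Sequence length in nucleotides (gaps excluded);
#'   derived from `sequence` when absent.
#' @param lineage Semicolon-separated lineage string
#'   (`superkingdom;phylum;class;order;family;genus;species`) or `NA`.
#' @param country Country of origin, or `NA` when unrecorded.
#' @param genbank_xref GenBank accession mirrored by a BOLD record;
#'   only meaningful when `source_db == "BOLD"`.
#' @return A one-row record table.
#' @export
sequence_record <- function(source_db, accession, organism, marker,
                            sequence = NA_character_,
                            seq_length = NA_integer_,
                            lineage = NA_character_,
                            country = NA_character_,
                            genbank_xref = NA_character_) {
  if (is.na(seq_length) && !is.na(sequence)) {
    seq_length <- nchar(gsub("-", "", sequence, fixed = TRUE))
  }
  as_records(data.frame(
    source_db = source_db, accession = accession, organism = organism,
    lineage = lineage, marker = marker, seq_length = as.integer(seq_length),
    country = country, genbank_xref = genbank_xref, sequence = sequence,
    stringsAsFactors = FALSE
  ))
}

#' Validate a sequence record against the domain invariants
#'
#' Checks: non-empty accession; known source database; `seq_length >= 1`;
#' sequence drawn from the IUPAC alphabet (plus gap); `seq_length` equal
#' to the ungapped sequence length when both are present; `genbank_xref`
#' only on BOLD records.
#'
#' @param rec A one-row record table (or a named list with the same
#'   fields).
#' @return A character vector of violation descriptions, empty when the
#'   record is valid. Violations name the offending field.
#' @export
validate_record <- function(rec) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1)
    rec <- as.list(rec)
  }
  v <- character(0)
  acc <- rec$accession
  if (is.null(acc) || is.na(acc) || !nzchar(trimws(acc))) {
    v <- c(v, "accession: must be non-empty")
  }
  if (!isTRUE(rec$source_db %in% SOURCE_DBS)) {
    v <- c(v, sprintf("source_db: must be one of %s",
                      paste(SOURCE_DBS, collapse = "/")))
  }
  len <- rec$seq_length
  if (!is.null(len) && !is.na(len) && len < 1) {
    v <- c(v, "seq_length: must be >= 1")
  }
  seq <- rec$sequence
  if (!is.null(seq) && !is.na(seq)) {
    chars <- unique(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, SEQ_ALPHABET)
    if (length(bad) > 0) {
      v <- c(v, sprintf("sequence: characters outside IUPAC alphabet (%s)",
                        paste(bad, collapse = "")))
    }
    ungapped <- nchar(gsub("-", "", seq, fixed = TRUE))
    if (!is.null(len) && !is.na(len) && len != ungapped) {
      v <- c(v, sprintf(
        "seq_length: recorded %d but sequence has %d ungapped bases",
        len, ungapped))
    }
  }
  xref <- rec$genbank_xref
  if (!is.null(xref) && !is.na(xref) && !identical(rec$source_db, "BOLD")) {
    v <- c(v, "genbank_xref: only meaningful on BOLD records")
  }
  v
}

## ---- barcode groups --------------------------------------------------

#' Construct a barcode group
#'
#' A barcode group is a canonical locus name plus the set of synonymous
#' marker spellings it aggregates (matched case-insensitively), e.g. the
#' CO1 group covering `COI`, `COX1`, `cytochrome c oxidase subunit I`.
#'
#' @param canonical Canonical locus name (e.g. `"CO1"`).
#' @param synonyms Character vector of synonymous spellings; the
#'   canonical name is always included and listed first.
#' @return An object of class `barcode_group`.
#' @export
barcode_group <- function(canonical, synonyms = character(0)) {
  canonical <- squish(canonical)
  stopifnot(nzchar(canonical))
  syns <- squish(as.character(synonyms))
  syns <- unique(c(canonical, syns[nzchar(syns)]))
  structure(list(canonical = canonical, synonyms = syns),
            class = "barcode_group")
}

#' @export
print.barcode_group <- function(x, ...) {
  cat(sprintf("<barcode group %s: %s>\n", x$canonical,
              paste(x$synonyms, collapse = ", ")))
  invisible(x)
}

# Distinct groups must not share a spelling, or normalization would be
# ambiguous; asserted whenever a group table is loaded.
check_groups <- function(groups) {
  stopifnot(length(groups) > 0)
  all_syn <- unlist(lapply(groups, function(g) tolower(g$synonyms)))
  dup <- unique(all_syn[duplicated(all_syn)])
  if (length(dup) > 0) {
    rc_abort("overlapping_groups",
             paste0("synonym(s) shared by multiple barcode groups: ",
                    paste(dup, collapse = ", ")))
  }
  invisible(groups)
}

#' Read a barcode-group table
#'
#' The table is a CSV with columns `canonical,synonym`, one row per
#' synonym spelling. Group order follows first appearance.
#'
#' @param path Path to the CSV file.
#' @return A named list of [barcode_group()] objects (names are the
#'   canonical locus names). Synonym sets are checked for disjointness.
#' @export
read_barcode_groups <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("canonical", "synonym") %in% names(df))) {
    rc_abort("malformed_csv",
             "barcode-group table needs columns canonical,synonym")
  }
  cans <- unique(df$canonical)
  groups <- lapply(cans, function(cn) {
    barcode_group(cn, df$synonym[df$canonical == cn])
  })
  names(groups) <- cans
  check_groups(groups)
  groups
}

.refcov_env <- new.env(parent = emptyenv())

#' Default barcode groups
#'
#' Groups for CO1, 16S, 18S, 12S (including the `Vert12S` spelling used
#' by CRUX database directories), FITS, PITS and trnL, shipped as
#' `extdata/barcode_groups.csv`. The synonym curation is this package's
#' own; extend it via [read_barcode_groups()] on a user table.
#'
#' @return A named list of [barcode_group()] objects.
#' @export
default_barcode_groups <- function() {
  if (is.null(.refcov_env$default_groups)) {
    path <- system.file("extdata", "barcode_groups.csv", package = "refcov")
    .refcov_env$default_groups <- read_barcode_groups(path)
  }
  .refcov_env$default_groups
}

#' Normalize a raw marker label into its barcode group
#'
#' Matching is a case-insensitive exact comparison on whitespace-trimmed
#' synonym strings — deliberately not substring matching, which would
#' silently mis-group labels like `"CO12"`.
#'
#' @param raw Character vector of raw marker/gene labels.
#' @param groups A list of [barcode_group()] objects (default:
#'   [default_barcode_groups()]).
#' @return Character vector of canonical names; `NA` where the label
#'   matches no group (unmatched is a value, not an error).
#' @export
#' @examples
#' normalize_marker(c("COI", "CO1", "rbcL"))
normalize_marker <- function(raw, groups = default_barcode_groups()) {
  if (inherits(groups, "barcode_group")) groups <- list(groups)
  check_groups(groups)
  map <- unlist(unname(lapply(groups, function(g) {
    stats::setNames(rep(g$canonical, length(g$synonyms)),
                    tolower(g$synonyms))
  })))
  out <- unname(map[norm_name(as.character(raw))])
  as.character(out)
}

#' Resolve user-supplied barcode labels to groups
#'
#' A label matching one of `groups`' synonym sets gets that group;
#' anything else becomes a singleton group of its own spelling.
#'
#' @param barcodes Character vector of barcode labels.
#' @param groups Barcode groups to match against.
#' @return A named list of [barcode_group()] objects (duplicates
#'   collapse to one group).
#' @export
groups_for_barcodes <- function(barcodes, groups = default_barcode_groups()) {
  canon <- normalize_marker(barcodes, groups)
  out <- lapply(seq_along(barcodes), function(i) {
    if (!is.na(canon[i])) groups[[canon[i]]] else barcode_group(barcodes[i])
  })
  names(out) <- vapply(out, function(g) g$canonical, character(1))
  out[!duplicated(names(out))]
}

## ---- lineage ---------------------------------------------------------

#' Parse a semicolon-separated lineage string
#'
#' @param x A string of up to 7 semicolon-separated rank names in the
#'   order superkingdom;phylum;class;order;family;genus;species. Blank
#'   fields become `NA`.
#' @return A named character vector over the fixed rank vocabulary.
#' @export
parse_lineage <- function(x) {
  out <- stats::setNames(rep(NA_character_, length(LINEAGE_RANKS)),
                         LINEAGE_RANKS)
  if (is.null(x) || length(x) == 0 || is.na(x)) return(out)
  parts <- squish(strsplit(paste0(x, ";\x01"), ";", fixed = TRUE)[[1]])
  parts <- parts[-length(parts)]
  n <- min(length(parts), length(LINEAGE_RANKS))
  out[seq_len(n)] <- parts[seq_len(n)]
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Serialize rank names into a lineage string
#'
#' @param ... Named rank values (e.g. `order = "Anura"`, `genus =
#'   "Xenopus"`, `species = "Xenopus laevis"`); unnamed ranks are blank.
#' @return A 7-field semicolon-separated lineage string.
#' @export
make_lineage <- function(...) {
  vals <- list(...)
  bad <- setdiff(names(vals), LINEAGE_RANKS)
  if (length(bad) > 0) {
    rc_abort("bad_lineage", paste0("unknown rank(s): ", paste(bad, collapse = ", ")))
  }
  out <- stats::setNames(rep("", length(LINEAGE_RANKS)), LINEAGE_RANKS)
  for (rk in names(vals)) out[rk] <- if (is.na(vals[[rk]])) "" else vals[[rk]]
  paste(out, collapse = ";")
}

## ---- filters ---------------------------------------------------------

#' Specify record-level search filters
#'
#' @param min_length,max_length Inclusive sequence-length bounds in
#'   nucleotides, or `NULL` for no bound.
#' @param countries Character vector of countries to keep (matched
#'   case-insensitively after trimming); records without a recorded
#'   country match only the reserved name `"Unspecified"`. `NULL`
#'   disables country filtering.
#' @param exclude_ncbi_duplicates Drop BOLD records whose GenBank
#'   cross-reference is also present in NCBI results (BOLD only).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_length = NULL, max_length = NULL,
                        countries = NULL, exclude_ncbi_duplicates = FALSE) {
  if (!is.null(min_length)) stopifnot(min_length >= 0)
  if (!is.null(min_length) && !is.null(max_length) &&
      min_length > max_length) {
    rc_abort("bad_filter", "min_length must be <= max_length")
  }
  structure(list(min_length = min_length, max_length = max_length,
                 countries = countries,
                 exclude_ncbi_duplicates = isTRUE(exclude_ncbi_duplicates)),
            class = "filter_spec")
}

## ---- organism query --------------------------------------------------

#' Construct an organism query
#'
#' Holds the user's input name plus any appended name corrections; the
#' original is never removed or edited (corrections are appended, per
#' the append-not-replace rule).
#'
#' @param input_name The name as supplied by the user.
#' @param corrections Zero or more corrected names to append (duplicates
#'   of the input are dropped).
#' @param log A data.frame with columns `original`, `correction`,
#'   `note`, one row per applied correction.
#' @return An object of class `organism_query`.
#' @export
organism_query <- function(input_name, corrections = character(0),
                           log = NULL) {
  input_name <- squish(input_name)
  stopifnot(length(input_name) == 1, !is.na(input_name),
            nzchar(input_name))
  corrections <- squish(as.character(corrections))
  resolved <- unique(c(input_name, corrections[nzchar(corrections)]))
  if (is.null(log)) {
    log <- data.frame(original = character(0), correction = character(0),
                      note = character(0), stringsAsFactors = FALSE)
  }
  structure(list(input_name = input_name, resolved_names = resolved,
                 resolution_log = log),
            class = "organism_query")
}

#' @export
print.organism_query <- function(x, ...) {
  cat(sprintf("<organism query \"%s\"", x$input_name))
  if (length(x$resolved_names) > 1) {
    cat(" +", paste(x$resolved_names[-1], collapse = ", "))
  }
  cat(">\n")
  invisible(x)
}

## ---- search statement ------------------------------------------------

#' Construct a search statement
#'
#' The literal query text submitted to a database, kept so users can
#' copy-paste it into the database's own web interface to validate
#' results.
#'
#' @param target_db Database the statement targets (`"NCBI"`, `"BOLD"`, ...).
#' @param text The literal query text (non-empty).
#' @param organism,barcode The organism and canonical barcode the
#'   statement was built for.
#' @return An object of class `search_statement`.
#' @export
search_statement <- function(target_db, text, organism, barcode) {
  stopifnot(nzchar(text))
  structure(list(target_db = target_db, text = text,
                 organism = organism, barcode = barcode),
            class = "search_statement")
}

#' @export
print.search_statement <- function(x, ...) {
  cat(sprintf("<%s statement (%s / %s)>\n%s\n",
              x$target_db, x$organism, x$barcode, x$text))
  invisible(x)
}
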