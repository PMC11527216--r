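# Offline snapshot source: a file-backed set of sequence records plus a
# taxonomy backbone, acting as a drop-in record source so the full
# workflow runs without network access.

#' Construct an offline snapshot source
#'
#' @param records A record table (see [empty_records()]); accessions
#'   must be unique.
#' @param backbone Taxonomy backbone: a data.frame with columns `name`
#'   and `lineage` (7-field semicolon lineage string). Organisms absent
#'   from the backbone are treated as unregistered by
#'   [lineage_of()]/[fallback_search()].
#' @param seed Optional integer recording the generator seed the
#'   snapshot was created with.
#' @return An object of class `snapshot_source`.
#' @export
snapshot_source <- function(records, backbone = NULL, seed = NULL) {
  records <- as_records(records)
  dup <- records$accession[duplicated(records$accession)]
  if (length(dup) > 0) {
    rc_abort("bad_records", paste0("duplicate accession(s): ",
                                   paste(unique(dup), collapse = ", ")))
  }
  if (is.null(backbone)) {
    backbone <- data.frame(name = character(0), lineage = character(0),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "lineage") %in% names(backbone)))
  backbone <- data.frame(name = as.character(backbone$name),
                         lineage = as.character(backbone$lineage),
                         stringsAsFactors = FALSE)
  structure(list(records = records, backbone = backbone, seed = seed),
            class = c("snapshot_source", "record_source"))
}

#' @export
print.snapshot_source <- function(x, ...) {
  cat(sprintf("<%s source: %d records, %d backbone taxa>\n",
              source_name(x), nrow(x$records), nrow(x$backbone)))
  invisible(x)
}

#' @export
source_name.snapshot_source <- function(src) "snapshot"

#' @export
source_capabilities.snapshot_source <- function(src) {
  c("COUNT", "FETCH", "SUBTREE_QUERY", "COUNTRY_METADATA")
}

#' @export
count_matches.snapshot_source <- function(src, organism, group,
                                          filters = filter_spec()) {
  nrow(match_records(src$records, organism, group, filters))
}

#' @export
fetch_records.snapshot_source <- function(src, organism, group,
                                          filters = filter_spec(),
                                          want_sequence = FALSE) {
  out <- match_records(src$records, organism, group, filters)
  out <- out[order(out$accession), , drop = FALSE]
  if (!want_sequence) out$sequence <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
count_subtree.snapshot_source <- function(src, rank, taxon, group,
                                          filters = filter_spec()) {
  stopifnot(rank %in% LINEAGE_RANKS)
  if (nrow(src$backbone) == 0) return(0L)
  at_rank <- vapply(src$backbone$lineage,
                    function(l) parse_lineage(l)[[rank]], character(1),
                    USE.NAMES = FALSE)
  members <- src$backbone$name[!is.na(at_rank) &
                                 norm_name(at_rank) == norm_name(taxon)]
  if (length(members) == 0) return(0L)
  recs <- src$records
  keep <- !is.na(recs$organism) &
    norm_name(recs$organism) %in% norm_name(members) &
    !is.na(recs$marker) &
    norm_name(recs$marker) %in% tolower(group$synonyms)
  recs <- recs[keep, , drop = FALSE]
  recs <- apply_length_filter(recs, filters$min_length, filters$max_length)
  recs <- apply_country_filter(recs, filters$countries)
  nrow(recs)
}

## ---- serialization ---------------------------------------------------

SNAPSHOT_HEADER <- paste(RECORD_COLS, collapse = "\t")

backbone_path_for <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_backbone.tsv")
}

#' Save a snapshot to disk
#'
#' Records go to `path` as a TSV with a fixed column order (header
#' required); the taxonomy backbone goes to a companion TSV
#' (`<path-sans-ext>_backbone.tsv` by default). Missing fields are
#' serialized as empty strings. Save-then-load is lossless.
#'
#' @param snapshot A [snapshot_source()].
#' @param path Output path for the record TSV.
#' @param backbone_path Output path for the backbone TSV.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(snapshot, path,
                          backbone_path = backbone_path_for(path)) {
  stopifnot(inherits(snapshot, "snapshot_source"))
  recs <- snapshot$records
  lines <- SNAPSHOT_HEADER
  if (!is.null(snapshot$seed)) {
    lines <- c(sprintf("# seed: %d", as.integer(snapshot$seed)), lines)
  }
  if (nrow(recs) > 0) {
    mat <- vapply(RECORD_COLS, function(col) {
      x <- as.character(recs[[col]])
      x[is.na(x)] <- ""
      x
    }, character(nrow(recs)))
    mat <- matrix(mat, nrow = nrow(recs))
    lines <- c(lines, apply(mat, 1, paste, collapse = "\t"))
  }
  writeLines(lines, path, sep = "\n")
  bb <- snapshot$backbone
  bb_lines <- c("name\tlineage",
                if (nrow(bb) > 0) paste(bb$name, bb$lineage, sep = "\t"))
  writeLines(bb_lines, backbone_path, sep = "\n")
  invisible(path)
}

#' Load a snapshot from disk
#'
#' @param path Path to a record TSV written by [save_snapshot()].
#' @param backbone_path Companion backbone TSV; an absent file loads an
#'   empty backbone.
#' @return A [snapshot_source()]. A malformed file (missing header,
#'   wrong field count) raises `refcov_malformed_snapshot` naming the
#'   offending line number.
#' @export
load_snapshot <- function(path, backbone_path = backbone_path_for(path)) {
  if (!file.exists(path)) {
    rc_abort("malformed_snapshot", sprintf("no such file: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  seed <- NULL
  off <- 0L
  if (length(lines) > 0 && grepl("^# seed:", lines[1])) {
    seed <- as.integer(sub("^# seed:\\s*", "", lines[1]))
    lines <- lines[-1]
    off <- 1L
  }
  if (length(lines) == 0 || lines[1] != SNAPSHOT_HEADER) {
    rc_abort("malformed_snapshot",
             sprintf("%s: line %d: missing or wrong header", path, off + 1L))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    recs <- empty_records()
  } else {
    fields <- strsplit(paste0(body, "\t\x01"), "\t", fixed = TRUE)
    nf <- lengths(fields) - 1L
    bad <- which(nf != length(RECORD_COLS))
    if (length(bad) > 0) {
      rc_abort("malformed_snapshot",
               sprintf("%s: line %d: expected %d fields, found %d",
                       path, bad[1] + 1L + off, length(RECORD_COLS),
                       nf[bad[1]]))
    }
    mat <- do.call(rbind, lapply(fields, function(f) f[seq_along(RECORD_COLS)]))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- RECORD_COLS
    df$seq_length <- suppressWarnings(as.integer(df$seq_length))
    recs <- as_records(df)
  }
  backbone <- NULL
  if (file.exists(backbone_path)) {
    bb_lines <- readLines(backbone_path, warn = FALSE)
    if (length(bb_lines) == 0 || bb_lines[1] != "name\tlineage") {
      rc_abort("malformed_snapshot",
               sprintf("%s: line 1: missing or wrong header", backbone_path))
    }
    bb_body <- bb_lines[-1]
    bb_body <- bb_body[nzchar(bb_body)]
    if (length(bb_body) > 0) {
      parts <- strsplit(paste0(bb_body, "\t\x01"), "\t", fixed = TRUE)
      npf <- lengths(parts) - 1L
      bad <- which(npf != 2L)
      if (length(bad) > 0) {
        rc_abort("malformed_snapshot",
                 sprintf("%s: line %d: expected 2 fields, found %d",
                         backbone_path, bad[1] + 1L, npf[bad[1]]))
      }
      backbone <- data.frame(
        name = vapply(parts, `[[`, character(1), 1L),
        lineage = vapply(parts, `[[`, character(1), 2L),
        stringsAsFactors = FALSE
      )
    }
  }
  snapshot_source(recs, backbone, seed = seed)
}
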