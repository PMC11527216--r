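# Coverage Matrix and Results Summary: the organisms x barcodes count
# grid (with rank-annotated fallback rows) and the per-barcode summary
# (sequence count, percentage share, organisms covered / missing), plus
# record-level filters, BOLD-vs-NCBI deduplication and country tallies.

#' Keep records within inclusive length bounds
#'
#' Records with no parseable length metadata are kept while no bound is
#' active, and dropped (with the drop counted in the
#' `dropped_missing_length` attribute) once a bound is set — dropping
#' them silently would hide coverage.
#'
#' @param recs A record table.
#' @param min,max Inclusive bounds in nucleotides; `NULL` for none.
#' @return Filtered record table; attribute `dropped_missing_length`
#'   counts records dropped solely for missing length metadata.
#' @export
apply_length_filter <- function(recs, min = NULL, max = NULL) {
  if (is.null(min) && is.null(max)) {
    attr(recs, "dropped_missing_length") <- 0L
    return(recs)
  }
  if (!is.null(min) && !is.null(max) && min > max) {
    rc_abort("bad_filter", "min length must be <= max length")
  }
  len <- recs$seq_length
  missing <- is.na(len)
  keep <- !missing
  if (!is.null(min)) keep <- keep & len >= min
  if (!is.null(max)) keep <- keep & len <= max
  keep[is.na(keep)] <- FALSE
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_missing_length") <- sum(missing)
  out
}

#' Keep records from given countries of origin
#'
#' Matching is case-insensitive on trimmed country names. Records with
#' no recorded country match only the reserved name `"Unspecified"`.
#'
#' @param recs A record table.
#' @param countries Countries to keep; `NULL` disables the filter (an
#'   empty set keeps nothing).
#' @return Filtered record table.
#' @export
apply_country_filter <- function(recs, countries = NULL) {
  if (is.null(countries)) return(recs)
  cty <- recs$country
  cty[is.na(cty)] <- "Unspecified"
  keep <- norm_name(cty) %in% norm_name(countries)
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove BOLD records mirrored in NCBI Nucleotide
#'
#' A BOLD record is a duplicate when its GenBank cross-reference —
#' version suffix stripped, since BOLD and NCBI disagree on version
#' notation — is present in the NCBI accession set. Records without a
#' cross-reference are always kept (no key to match).
#'
#' @param bold_recs Record table of BOLD records.
#' @param ncbi_accessions Character vector of NCBI accessions (versions
#'   are stripped before matching).
#' @return A list with record tables `kept` and `removed` (input order
#'   preserved; disjoint; their union is the input).
#' @export
dedupe_cross_db <- function(bold_recs, ncbi_accessions) {
  strip <- function(x) sub("\\.[0-9]+$", "", x)
  key <- strip(bold_recs$genbank_xref)
  dup <- !is.na(key) & key %in% strip(ncbi_accessions)
  kept <- bold_recs[!dup, , drop = FALSE]
  removed <- bold_recs[dup, , drop = FALSE]
  rownames(kept) <- NULL
  rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Tally records by country of origin
#'
#' @param recs A record table.
#' @return A data.frame with one row per distinct country (absent
#'   country reported as `"Unspecified"`): `country`, `n_records`,
#'   `n_organisms`; sorted by `n_records` descending, then name.
#' @export
country_tally <- function(recs) {
  if (nrow(recs) == 0) {
    return(data.frame(country = character(0), n_records = integer(0),
                      n_organisms = integer(0), stringsAsFactors = FALSE))
  }
  cty <- trimws(recs$country)
  cty[is.na(cty) | cty == ""] <- "Unspecified"
  out <- do.call(rbind, lapply(unique(cty), function(cc) {
    sel <- cty == cc
    data.frame(country = cc, n_records = sum(sel),
               n_organisms = length(unique(norm_name(recs$organism[sel]))),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_records, out$country), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- coverage matrix -------------------------------------------------

#' Build the Coverage Matrix
#'
#' One row per input organism, one column per barcode group; each cell
#' is the number of sequences found for that organism-barcode pair,
#' pooled over the organism's resolved names. Zeros reveal reference
#' gaps. With `enable_fallback`, any zero cell triggers a rank-fallback
#' search ([fallback_search()]) whose genus/family/order counts are
#' collected as annotated fallback rows; an organism missing from the
#' backbone keeps its all-zero row, is flagged `UNREGISTERED`, and gets
#' no fallback rows. A failing source marks the organism
#' `SOURCE_ERROR` and leaves the cell `NA` — absent, never zero.
#'
#' @param src A record source.
#' @param queries A list of [organism_query()] objects (bare names are
#'   accepted), non-empty.
#' @param groups A list of [barcode_group()] objects, non-empty.
#' @param filters A [filter_spec()].
#' @param enable_fallback Run rank-fallback searches for zero cells.
#' @param backbone Taxonomy backbone for fallback (defaults to the
#'   source's own backbone when it has one).
#' @return An object of class `coverage_matrix`: list with `organisms`,
#'   `barcodes`, `cells` (integer matrix, `NA` = failed search),
#'   `fallback_rows` (data.frame `organism`, `rank`, `taxon`,
#'   `barcode`, `count`) and `flags` (named list; per-organism subset
#'   of `UNREGISTERED`, `CORRECTED`, `SOURCE_ERROR`).
#' @export
build_coverage_matrix <- function(src, queries, groups,
                                  filters = filter_spec(),
                                  enable_fallback = FALSE,
                                  backbone = NULL) {
  if (is.character(queries)) queries <- resolve_names(queries)
  if (inherits(queries, "organism_query")) queries <- list(queries)
  if (inherits(groups, "barcode_group")) groups <- list(groups)
  stopifnot(length(queries) > 0, length(groups) > 0)
  queries <- lapply(queries, function(q) {
    if (is.character(q)) organism_query(q) else q
  })
  if (is.null(backbone) && inherits(src, "snapshot_source")) {
    backbone <- src$backbone
  }
  organisms <- unname(vapply(queries, function(q) q$input_name,
                             character(1)))
  barcodes <- unname(vapply(groups, function(g) g$canonical,
                            character(1)))
  cells <- matrix(NA_integer_, nrow = length(organisms),
                  ncol = length(barcodes),
                  dimnames = list(organisms, barcodes))
  flags <- stats::setNames(vector("list", length(organisms)), organisms)
  flags[] <- list(character(0))
  fb <- data.frame(organism = character(0), rank = character(0),
                   taxon = character(0), barcode = character(0),
                   count = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    if (length(q$resolved_names) > 1) {
      flags[[i]] <- union(flags[[i]], "CORRECTED")
    }
    for (j in seq_along(groups)) {
      n <- tryCatch({
        total <- 0L
        for (nm in q$resolved_names) {
          total <- total + count_matches(src, nm, groups[[j]], filters)
        }
        total
      }, refcov_source_unavailable = function(e) NA_integer_)
      cells[i, j] <- n
      if (is.na(n)) {
        flags[[i]] <- union(flags[[i]], "SOURCE_ERROR")
        next
      }
      if (enable_fallback && n == 0L) {
        fs <- fallback_search(src, q, groups[[j]], backbone, filters)
        if (isTRUE(attr(fs, "unregistered"))) {
          flags[[i]] <- union(flags[[i]], "UNREGISTERED")
        } else {
          anc <- fs[fs$rank != "species", , drop = FALSE]
          if (nrow(anc) > 0) {
            fb <- rbind(fb, data.frame(
              organism = q$input_name, rank = anc$rank, taxon = anc$taxon,
              barcode = barcodes[j], count = anc$count,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  # canonical order: input organism, rank ladder, barcode column order —
  # matches the CSV layout so write/read round-trips are exact
  if (nrow(fb) > 0) {
    fb <- fb[order(match(fb$organism, organisms),
                   match(fb$rank, c("species", "genus", "family",
                                    "order", "class")),
                   match(fb$barcode, barcodes)), , drop = FALSE]
    rownames(fb) <- NULL
  }
  structure(list(organisms = organisms, barcodes = barcodes,
                 cells = cells, fallback_rows = fb, flags = flags,
                 queries = queries),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("Coverage matrix: %d organisms x %d barcodes\n",
              length(x$organisms), length(x$barcodes)))
  print(x$cells)
  flagged <- names(x$flags)[lengths(x$flags) > 0]
  for (o in flagged) {
    cat(sprintf("  %s: %s\n", o, paste(x$flags[[o]], collapse = ", ")))
  }
  if (nrow(x$fallback_rows) > 0) {
    cat(sprintf("%d fallback row(s) at broader ranks\n",
                nrow(x$fallback_rows)))
  }
  invisible(x)
}

# display convention: half-up to 1 decimal, from raw counts
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Summarize a Coverage Matrix per barcode
#'
#' One row per barcode: sequences found, the percentage of all found
#' sequences this barcode accounts for (half-up rounded to 1 decimal,
#' computed from raw counts), organisms with at least one sequence, and
#' organisms with none. Fallback rows are excluded — the summary counts
#' species-rank cells only, so ranks are never mixed. `NA` cells
#' (failed searches) are excluded from sums, not treated as zero.
#'
#' @param object A `coverage_matrix`.
#' @param ... Unused.
#' @return A `coverage_summary` data.frame with columns `barcode`,
#'   `n_sequences`, `pct_of_total`, `n_organisms_covered`,
#'   `n_organisms_missing`, plus attributes `total_sequences`,
#'   `total_organisms_detected` and `n_organisms`.
#' @export
summary.coverage_matrix <- function(object, ...) {
  cells <- object$cells
  n_org <- nrow(cells)
  n_seq <- as.integer(colSums(cells, na.rm = TRUE))
  total <- sum(n_seq)
  pct <- if (total > 0) round_half_up1(100 * n_seq / total) else
    rep(0, length(n_seq))
  covered <- as.integer(colSums(cells > 0, na.rm = TRUE))
  detected <- sum(rowSums(cells > 0, na.rm = TRUE) > 0)
  out <- data.frame(
    barcode = object$barcodes, n_sequences = n_seq, pct_of_total = pct,
    n_organisms_covered = covered,
    n_organisms_missing = n_org - covered,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, total_sequences = total,
            total_organisms_detected = as.integer(detected),
            n_organisms = n_org,
            class = c("coverage_summary", "data.frame"))
}

#' @export
print.coverage_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total sequences: %d; organisms detected: %d of %d\n",
              attr(x, "total_sequences"),
              attr(x, "total_organisms_detected"),
              attr(x, "n_organisms")))
  invisible(x)
}
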