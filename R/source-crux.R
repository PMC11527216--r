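# Local CRUX-style reference databases: a directory holding one
# subdatabase per barcode, each a FASTA file plus an accession->lineage
# taxonomy table (`<barcode>.fasta` + `<barcode>_taxonomy.txt`, the
# Anacapa/CRUX convention). An audit against a CRUX source always
# reports every subdatabase present, zeros included.

#' Load a CRUX-style reference database directory
#'
#' Each subdatabase contributes records whose `marker` is the
#' subdatabase's barcode name and whose `organism` is the species field
#' of the taxonomy lineage. Malformed entries (taxonomy line without 7
#' semicolon-separated rank fields; FASTA identifier missing from the
#' taxonomy table) are skipped and reported per entry — loading
#' continues.
#'
#' @param dir_path Directory containing at least one
#'   `<barcode>.fasta` + `<barcode>_taxonomy.txt` pair.
#' @return A `crux_source` (inherits `snapshot_source`), with elements
#'   `barcodes` (subdatabase names found, in sorted order) and
#'   `malformed` (data.frame of skipped entries: `file`, `accession`,
#'   `reason`). A `refcov_malformed_db` warning summarizes skips.
#' @export
load_crux_database <- function(dir_path) {
  if (!dir.exists(dir_path)) {
    rc_abort("malformed_db", sprintf("no such directory: %s", dir_path))
  }
  tax_files <- sort(list.files(dir_path, pattern = "_taxonomy\\.txt$"))
  barcodes <- sub("_taxonomy\\.txt$", "", tax_files)
  has_fasta <- file.exists(file.path(dir_path, paste0(barcodes, ".fasta")))
  barcodes <- barcodes[has_fasta]
  if (length(barcodes) == 0) {
    rc_abort("malformed_db", sprintf(
      "%s: no <barcode>.fasta + <barcode>_taxonomy.txt pairs found",
      dir_path))
  }
  malformed <- data.frame(file = character(0), accession = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  all_recs <- list()
  backbone <- list()
  for (bc in barcodes) {
    fa_path <- file.path(dir_path, paste0(bc, ".fasta"))
    tx_path <- file.path(dir_path, paste0(bc, "_taxonomy.txt"))
    seqs <- Biostrings::readDNAStringSet(fa_path)
    acc <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L)
    tx_lines <- readLines(tx_path, warn = FALSE)
    tx_lines <- tx_lines[nzchar(tx_lines)]
    tx_parts <- strsplit(tx_lines, "\t", fixed = TRUE)
    tax <- list()
    bad_acc <- character(0)
    for (i in seq_along(tx_parts)) {
      p <- tx_parts[[i]]
      if (length(p) != 2) {
        malformed <- rbind(malformed, data.frame(
          file = basename(tx_path), accession = p[1] %||% "?",
          reason = "taxonomy line is not accession<TAB>lineage",
          stringsAsFactors = FALSE))
        next
      }
      ranks <- strsplit(paste0(p[2], ";\x01"), ";", fixed = TRUE)[[1]]
      ranks <- ranks[-length(ranks)]
      if (length(ranks) != 7) {
        malformed <- rbind(malformed, data.frame(
          file = basename(tx_path), accession = p[1],
          reason = sprintf("lineage has %d rank fields, expected 7",
                           length(ranks)),
          stringsAsFactors = FALSE))
        bad_acc <- c(bad_acc, p[1])
        next
      }
      tax[[p[1]]] <- p[2]
    }
    known <- acc %in% names(tax)
    # an accession already reported for a bad taxonomy line is not
    # reported again as missing
    for (a in setdiff(acc[!known], bad_acc)) {
      malformed <- rbind(malformed, data.frame(
        file = basename(fa_path), accession = a,
        reason = "FASTA identifier missing from taxonomy table",
        stringsAsFactors = FALSE))
    }
    if (any(known)) {
      keep_acc <- acc[known]
      lineages <- unlist(tax[keep_acc], use.names = FALSE)
      species <- vapply(lineages,
                        function(l) parse_lineage(l)[["species"]],
                        character(1), USE.NAMES = FALSE)
      seq_txt <- as.character(seqs[known])
      all_recs[[bc]] <- data.frame(
        source_db = "CRUX", accession = keep_acc, organism = species,
        lineage = lineages, marker = bc,
        seq_length = nchar(gsub("-", "", seq_txt, fixed = TRUE)),
        country = NA_character_, genbank_xref = NA_character_,
        sequence = seq_txt, stringsAsFactors = FALSE)
      ok_sp <- !is.na(species)
      backbone[[bc]] <- data.frame(name = species[ok_sp],
                                   lineage = lineages[ok_sp],
                                   stringsAsFactors = FALSE)
    }
  }
  recs <- if (length(all_recs) > 0) {
    as_records(do.call(rbind, all_recs))
  } else {
    empty_records()
  }
  bb <- if (length(backbone) > 0) {
    b <- do.call(rbind, backbone)
    b[!duplicated(norm_name(b$name)), , drop = FALSE]
  } else NULL
  src <- snapshot_source(recs, bb)
  src$barcodes <- barcodes
  src$malformed <- malformed
  class(src) <- c("crux_source", class(src))
  if (nrow(malformed) > 0) {
    rc_warn("malformed_db",
            sprintf("%s: skipped %d malformed entr%s (see $malformed)",
                    dir_path, nrow(malformed),
                    if (nrow(malformed) == 1) "y" else "ies"))
  }
  src
}

#' @export
source_name.crux_source <- function(src) "crux"

#' Barcode groups covered by a CRUX source
#'
#' Every subdatabase present in the directory maps to a group — via the
#' default synonym table when the subdatabase name matches one (e.g.
#' `Vert12S` joins the 12S group), otherwise as a singleton group — so
#' audits report a per-barcode breakdown covering all subdatabases,
#' zeros included.
#'
#' @param src A `crux_source`.
#' @param groups Barcode groups used for name normalization.
#' @return A named list of [barcode_group()] objects.
#' @export
crux_barcode_groups <- function(src, groups = default_barcode_groups()) {
  stopifnot(inherits(src, "crux_source"))
  groups_for_barcodes(src$barcodes, groups)
}
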