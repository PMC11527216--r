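# Per-barcode FASTA bundle: one <barcode>.fasta per non-empty barcode,
# packed into a zip. The zip is written by this package (STORE method,
# fixed 1980-01-01 DOS timestamp, own CRC32) so identical inputs give
# byte-identical archives — external zip tools embed wall-clock
# timestamps, which would break writer determinism. The manifest, not
# the archive, carries the creation time.

crc32_table <- function() {
  if (is.null(.refcov_env$crc_table)) {
    tab <- integer(256)
    # 0xEDB88320 as a signed 32-bit integer
    poly <- -306674912L
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(poly, bitwShiftR(c, 1L))
        } else {
          bitwShiftR(c, 1L)
        }
      }
      tab[n + 1] <- c
    }
    .refcov_env$crc_table <- tab
  }
  .refcov_env$crc_table
}

crc32 <- function(data) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(data)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

u16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L %% 256L))
}

u32 <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 2^32
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 2^16 %% 256, x %/% 2^24 %% 256))
}

# Minimal STORE-only zip. `files` is a named list of character content;
# DOS date fixed to 1980-01-01 00:00 for reproducibility.
zip_create <- function(path, files) {
  stopifnot(length(files) > 0, !is.null(names(files)))
  locals <- list()
  centrals <- list()
  offset <- 0
  dos_date <- u16(33L) # 1980-01-01
  dos_time <- u16(0L)
  for (nm in names(files)) {
    data <- charToRaw(files[[nm]])
    name <- charToRaw(nm)
    crc <- crc32(data)
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20L), u16(0L),
               u16(0L), dos_time, dos_date, u32(crc),
               u32(length(data)), u32(length(data)), u16(length(name)),
               u16(0L), name, data)
    central <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20L), u16(20L),
                 u16(0L), u16(0L), dos_time, dos_date, u32(crc),
                 u32(length(data)), u32(length(data)), u16(length(name)),
                 u16(0L), u16(0L), u16(0L), u16(0L), u32(0L),
                 u32(offset), name)
    locals[[nm]] <- local
    centrals[[nm]] <- central
    offset <- offset + length(local)
  }
  cd <- do.call(c, centrals)
  n <- length(files)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0L), u16(0L),
            u16(n), u16(n), u32(length(cd)), u32(offset), u16(0L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(c(do.call(c, locals), cd, eocd), con)
  invisible(path)
}

wrap80 <- function(s) {
  n <- nchar(s)
  starts <- seq.int(1L, n, by = 80L)
  substring(s, starts, pmin(starts + 79L, n))
}

# FASTA serialization: one blank line between records, 80-column
# wrapping — valid input for the usual alignment suites.
format_fasta <- function(recs) {
  entries <- vapply(seq_len(nrow(recs)), function(i) {
    paste(c(sprintf(">%s %s %s %s", recs$accession[i], recs$organism[i],
                    recs$marker[i], recs$source_db[i]),
            wrap80(recs$sequence[i])),
          collapse = "\n")
  }, character(1))
  paste0(paste(entries, collapse = "\n\n"), "\n")
}

#' Write a per-barcode FASTA zip bundle
#'
#' One `<canonical_barcode>.fasta` per barcode with at least one
#' record; empty barcodes are omitted. Each FASTA record has the header
#' `><accession> <organism> <marker> <source_db>`, the sequence wrapped
#' at 80 columns, records accession-sorted and separated by one blank
#' line. The archive bytes are identical across runs with equal inputs.
#'
#' @param records_by_barcode Named list mapping canonical barcode name
#'   to a record table; every record must carry sequence text.
#' @param path Output zip path.
#' @return The manifest: a data.frame with `barcode`, `n_records`,
#'   `file_size` (bytes), plus a `created` attribute (the one place a
#'   timestamp lives). No records at all raises `refcov_empty_input`
#'   and writes nothing.
#' @export
write_fasta_zip <- function(records_by_barcode, path) {
  stopifnot(is.list(records_by_barcode))
  keep <- vapply(records_by_barcode, function(r) NROW(r) > 0, logical(1))
  records_by_barcode <- records_by_barcode[keep]
  if (length(records_by_barcode) == 0) {
    rc_abort("empty_input", "no records to bundle; zip not written")
  }
  files <- list()
  manifest <- list()
  for (bc in names(records_by_barcode)) {
    recs <- records_by_barcode[[bc]]
    if (anyNA(recs$sequence)) {
      rc_abort("empty_input", sprintf(
        "barcode %s: %d record(s) lack sequence text", bc,
        sum(is.na(recs$sequence))))
    }
    recs <- recs[order(recs$accession), , drop = FALSE]
    content <- format_fasta(recs)
    files[[paste0(bc, ".fasta")]] <- content
    manifest[[bc]] <- data.frame(barcode = bc, n_records = nrow(recs),
                                 file_size = nchar(content, type = "bytes"),
                                 stringsAsFactors = FALSE)
  }
  zip_create(path, files)
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  attr(out, "created") <- format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ")
  out
}
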