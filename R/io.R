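# Readers/writers for the query CSV template and result artifacts.
# Every writer is deterministic: fixed field order, LF line endings, no
# timestamps in file content — identical inputs give byte-identical
# files, so results diff cleanly across runs.

csv_field <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs], fixed = TRUE), '"')
  x
}

write_csv_lines <- function(rows, path) {
  lines <- vapply(rows, function(r) paste(csv_field(r), collapse = ","),
                  character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL,
            useBytes = TRUE)
  invisible(path)
}

#' Read a query CSV
#'
#' Template: a header row `organism,barcode`, then one organism name
#' and/or barcode label per row. The two columns are independently
#' ragged — blank cells are skipped — so 11 organisms and 2 barcodes is
#' a perfectly shaped file. Order is preserved; duplicates are removed
#' with a warning. An empty barcode column means "use all default
#' barcode groups" for NCBI/BOLD (a CRUX source always audits every
#' subdatabase it has).
#'
#' @param path Path to the CSV file.
#' @return A list with character vectors `organisms` (length >= 1) and
#'   `barcodes` (possibly empty). A missing header or zero organisms
#'   raises `refcov_malformed_csv`.
#' @export
read_query_csv <- function(path) {
  if (!file.exists(path)) {
    rc_abort("malformed_csv", sprintf("no such file: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) rc_abort("malformed_csv", conditionMessage(e)))
  if (!"organism" %in% names(df)) {
    rc_abort("malformed_csv",
             sprintf("%s: header must contain an 'organism' column", path))
  }
  pick <- function(col) {
    if (!col %in% names(df)) return(character(0))
    vals <- squish(df[[col]])
    rows <- which(!is.na(vals) & nzchar(vals))
    vals <- vals[rows]
    dup <- duplicated(norm_name(vals))
    if (any(dup)) {
      rc_warn("duplicate_rows", sprintf(
        "%s: dropped duplicate %s value(s) at data row(s) %s",
        path, col, paste(rows[dup], collapse = ", ")))
    }
    vals[!dup]
  }
  organisms <- pick("organism")
  if (length(organisms) == 0) {
    rc_abort("malformed_csv", sprintf("%s: no organisms listed", path))
  }
  list(organisms = organisms, barcodes = pick("barcode"))
}

## ---- coverage matrix CSV ---------------------------------------------

FALLBACK_ROW_RE <- "^(species|genus|family|order|class): "

#' Write a Coverage Matrix to CSV
#'
#' Layout: first column `organism`, one column per barcode, a `flags`
#' column last. Fallback rows appear beneath their organism as
#' `<rank>: <taxon>`, with counts only in the barcode columns where the
#' fallback was computed. `NA` cells (failed searches) are written as
#' `NA`, never as 0.
#'
#' @param cm A `coverage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(cm, path) {
  rows <- list(c("organism", cm$barcodes, "flags"))
  for (i in seq_along(cm$organisms)) {
    o <- cm$organisms[i]
    vals <- cm$cells[i, ]
    vals_chr <- ifelse(is.na(vals), "NA", as.character(vals))
    rows[[length(rows) + 1]] <-
      c(o, vals_chr, paste(cm$flags[[i]], collapse = ";"))
    fbo <- cm$fallback_rows[cm$fallback_rows$organism == o, , drop = FALSE]
    if (nrow(fbo) > 0) {
      combos <- unique(fbo[c("rank", "taxon")])
      ladder <- match(combos$rank, c("species", "genus", "family",
                                     "order", "class"))
      combos <- combos[order(ladder), , drop = FALSE]
      for (k in seq_len(nrow(combos))) {
        rk <- combos$rank[k]
        tx <- combos$taxon[k]
        cnts <- vapply(cm$barcodes, function(b) {
          sel <- fbo$rank == rk & fbo$taxon == tx & fbo$barcode == b
          if (any(sel)) as.character(fbo$count[sel][1]) else ""
        }, character(1))
        rows[[length(rows) + 1]] <- c(sprintf("%s: %s", rk, tx), cnts, "")
      }
    }
  }
  write_csv_lines(rows, path)
}

#' Read back a Coverage Matrix CSV
#'
#' @param path A CSV written by [write_matrix_csv()].
#' @return A `coverage_matrix` with the same cells, fallback rows and
#'   flags (queries are rebuilt as identity queries).
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = "NA")
  stopifnot(names(df)[1] == "organism", names(df)[ncol(df)] == "flags")
  barcodes <- names(df)[-c(1, ncol(df))]
  is_fb <- grepl(FALLBACK_ROW_RE, df$organism)
  orows <- which(!is_fb)
  organisms <- df$organism[orows]
  cells <- matrix(NA_integer_, nrow = length(organisms),
                  ncol = length(barcodes),
                  dimnames = list(organisms, barcodes))
  for (j in seq_along(barcodes)) {
    cells[, j] <- suppressWarnings(as.integer(df[[barcodes[j]]][orows]))
  }
  flags <- lapply(df$flags[orows], function(f) {
    if (is.na(f) || !nzchar(f)) character(0) else
      strsplit(f, ";", fixed = TRUE)[[1]]
  })
  names(flags) <- organisms
  fb <- data.frame(organism = character(0), rank = character(0),
                   taxon = character(0), barcode = character(0),
                   count = integer(0), stringsAsFactors = FALSE)
  cur <- NA_character_
  for (r in seq_len(nrow(df))) {
    if (!is_fb[r]) {
      cur <- df$organism[r]
      next
    }
    m <- regmatches(df$organism[r],
                    regexec("^([a-z]+): (.*)$", df$organism[r]))[[1]]
    for (b in barcodes) {
      val <- df[[b]][r]
      if (!is.na(val) && nzchar(val)) {
        fb <- rbind(fb, data.frame(organism = cur, rank = m[2],
                                   taxon = m[3], barcode = b,
                                   count = as.integer(val),
                                   stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(organisms = organisms, barcodes = barcodes,
                 cells = cells, fallback_rows = fb, flags = flags,
                 queries = lapply(organisms, organism_query)),
            class = "coverage_matrix")
}

## ---- summary CSV -----------------------------------------------------

#' Write a Results Summary to CSV
#'
#' The four per-barcode columns in display order (sequences found,
#' percentage of total, organisms covered, organisms missing) plus a
#' `TOTAL` footer row carrying total sequences and total organisms
#' detected.
#'
#' @param st A `coverage_summary` (see [summary.coverage_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(st, path) {
  rows <- list(c("barcode", "n_sequences", "pct_of_total",
                 "n_organisms_covered", "n_organisms_missing"))
  for (i in seq_len(nrow(st))) {
    rows[[length(rows) + 1]] <- c(
      st$barcode[i], st$n_sequences[i], sprintf("%.1f", st$pct_of_total[i]),
      st$n_organisms_covered[i], st$n_organisms_missing[i])
  }
  rows[[length(rows) + 1]] <- c(
    "TOTAL", attr(st, "total_sequences"), "",
    attr(st, "total_organisms_detected"),
    attr(st, "n_organisms"))
  write_csv_lines(rows, path)
}

#' Read back a Results Summary CSV
#'
#' @param path A CSV written by [write_summary_csv()].
#' @return A `coverage_summary` data.frame with its totals attributes.
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  tot <- df[df$barcode == "TOTAL", , drop = FALSE]
  df <- df[df$barcode != "TOTAL", , drop = FALSE]
  out <- data.frame(
    barcode = df$barcode,
    n_sequences = as.integer(df$n_sequences),
    pct_of_total = as.numeric(df$pct_of_total),
    n_organisms_covered = as.integer(df$n_organisms_covered),
    n_organisms_missing = as.integer(df$n_organisms_missing),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            total_sequences = as.integer(tot$n_sequences[1]),
            total_organisms_detected = as.integer(tot$n_organisms_covered[1]),
            n_organisms = as.integer(tot$n_organisms_missing[1]),
            class = c("coverage_summary", "data.frame"))
}

#' Write a country tally to CSV
#'
#' @param tally A data.frame from [country_tally()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  rows <- c(list(c("country", "n_records", "n_organisms")),
            lapply(seq_len(nrow(tally)), function(i) {
              c(tally$country[i], tally$n_records[i], tally$n_organisms[i])
            }))
  write_csv_lines(rows, path)
}
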