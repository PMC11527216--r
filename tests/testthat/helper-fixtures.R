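# Shared fixtures, built in code at test time.

groups <- default_barcode_groups()
co1 <- groups$CO1
s16 <- groups$`16S`

# small hand-built record table
make_recs <- function(n = 6, organism = "Xenopus laevis", marker = "COI",
                      source_db = "SNAPSHOT", seed = 42) {
  withr::with_seed(seed, {
    lens <- sample(100:900, n, replace = TRUE)
    as_records(data.frame(
      source_db = source_db,
      accession = sprintf("TST%05d", seq_len(n)),
      organism = organism, lineage = NA_character_, marker = marker,
      seq_length = lens,
      country = sample(c("Iceland", "Chile", NA), n, replace = TRUE),
      genbank_xref = NA_character_,
      sequence = vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE))
  })
}

# snapshot with two congeneric frogs + one fish; backbone registered for
# all but "Ghostus absentus"
tiny_snapshot <- function() {
  recs <- rbind(
    make_recs(3, "Xenopus laevis", "COI"),
    within(make_recs(4, "Xenopus tropicalis", "CO1"), {
      accession <- sprintf("TRP%05d", 1:4)
    }),
    within(make_recs(2, "Xenopus laevis", "16S rRNA"), {
      accession <- sprintf("SIX%05d", 1:2)
    }),
    within(make_recs(5, "Ctenopharyngodon idella", "COX1"), {
      accession <- sprintf("FSH%05d", 1:5)
    }))
  backbone <- data.frame(
    name = c("Xenopus laevis", "Xenopus tropicalis", "Xenopus borealis",
             "Ctenopharyngodon idella"),
    lineage = c(
      "Eukaryota;Chordata;Amphibia;Anura;Pipidae;Xenopus;Xenopus laevis",
      "Eukaryota;Chordata;Amphibia;Anura;Pipidae;Xenopus;Xenopus tropicalis",
      "Eukaryota;Chordata;Amphibia;Anura;Pipidae;Xenopus;Xenopus borealis",
      "Eukaryota;Chordata;Actinopterygii;Cypriniformes;Xenocyprididae;Ctenopharyngodon;Ctenopharyngodon idella"),
    stringsAsFactors = FALSE)
  snapshot_source(as_records(recs), backbone)
}

# independent brute-force predicate scan: the oracle the sources must
# agree with (kept deliberately separate from match_records)
brute_count <- function(records, organism, synonyms, min_len = NULL,
                        max_len = NULL, countries = NULL) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    org <- records$organism[i]
    if (is.na(org) ||
        tolower(gsub("[[:space:]]+", " ", trimws(org))) !=
        tolower(gsub("[[:space:]]+", " ", trimws(organism)))) next
    mk <- records$marker[i]
    if (is.na(mk) ||
        !(tolower(trimws(mk)) %in% tolower(synonyms))) next
    len <- records$seq_length[i]
    if (!is.null(min_len) || !is.null(max_len)) {
      if (is.na(len)) next
      if (!is.null(min_len) && len < min_len) next
      if (!is.null(max_len) && len > max_len) next
    }
    if (!is.null(countries)) {
      cty <- records$country[i]
      if (is.na(cty)) cty <- "Unspecified"
      if (!(tolower(trimws(cty)) %in% tolower(trimws(countries)))) next
    }
    n <- n + 1L
  }
  n
}

# a source whose count always fails, for SOURCE_ERROR paths
failing_source <- function() {
  structure(list(), class = c("failing_source", "record_source"))
}

count_matches.failing_source <- function(src, organism, group,
                                         filters = filter_spec()) {
  refcov:::rc_abort("source_unavailable", "injected failure")
}
registerS3method("count_matches", "failing_source",
                 count_matches.failing_source,
                 envir = asNamespace("refcov"))

# write a small CRUX directory fixture: CO1 (5 records, one malformed
# taxonomy line -> 4 usable + 1 skip... see args), 16S (3 records)
write_crux_fixture <- function(dir, malformed_co1 = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- function(acc, n = 480) {
    withr::with_seed(sum(utf8ToInt(acc)), {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
            collapse = "")
    })
  }
  co1_acc <- sprintf("CRX%03d", 1:5)
  fa <- unlist(lapply(co1_acc, function(a) c(paste0(">", a), seqs(a))))
  writeLines(fa, file.path(dir, "CO1.fasta"))
  lin <- function(sp, gen, fam, ord) {
    sprintf("Eukaryota;Chordata;Amphibia;%s;%s;%s;%s", ord, fam, gen, sp)
  }
  tax <- c(
    paste0(co1_acc[1], "\t", lin("Xenopus laevis", "Xenopus", "Pipidae", "Anura")),
    paste0(co1_acc[2], "\t", lin("Xenopus laevis", "Xenopus", "Pipidae", "Anura")),
    paste0(co1_acc[3], "\t", lin("Eleutherodactylus coqui",
                                 "Eleutherodactylus",
                                 "Eleutherodactylidae", "Anura")),
    paste0(co1_acc[4], "\t", lin("Eleutherodactylus coqui",
                                 "Eleutherodactylus",
                                 "Eleutherodactylidae", "Anura")),
    if (malformed_co1) {
      paste0(co1_acc[5], "\tEukaryota;Chordata;Amphibia;Anura;Pipidae")
    } else {
      paste0(co1_acc[5], "\t", lin("Xenopus laevis", "Xenopus", "Pipidae",
                                   "Anura"))
    })
  writeLines(tax, file.path(dir, "CO1_taxonomy.txt"))
  s16_acc <- sprintf("SIX%03d", 1:3)
  fa16 <- unlist(lapply(s16_acc, function(a) c(paste0(">", a), seqs(a, 300))))
  writeLines(fa16, file.path(dir, "16S.fasta"))
  tax16 <- paste0(s16_acc, "\t",
                  lin("Xenopus laevis", "Xenopus", "Pipidae", "Anura"))
  writeLines(tax16, file.path(dir, "16S_taxonomy.txt"))
  invisible(dir)
}

write_query_fixture <- function(path, organisms,
                                barcodes = character(0)) {
  n <- max(length(organisms), length(barcodes))
  org <- c(organisms, rep("", n - length(organisms)))
  bc <- c(barcodes, rep("", n - length(barcodes)))
  writeLines(c("organism,barcode", paste(org, bc, sep = ",")), path)
  invisible(path)
}
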