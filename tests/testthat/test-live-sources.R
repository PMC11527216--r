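# Live-source code paths exercised offline through canned-response
# transports (no network is ever touched).

param <- function(url, key) {
  m <- regmatches(url, regexec(paste0("[?&]", key, "=([^&]*)"), url))[[1]]
  if (length(m) < 2) NA_character_ else utils::URLdecode(m[2])
}

# a fake E-utilities endpoint holding `n` ids for one organism/marker
fake_ncbi_transport <- function(n = 5, calls = new.env()) {
  calls$n <- 0L
  ids <- sprintf("90000%02d", seq_len(n))
  function(url) {
    calls$n <- calls$n + 1L
    if (grepl("esearch", url)) {
      term <- param(url, "term")
      count <- if (grepl("Xenopus laevis", term, fixed = TRUE)) n else 0L
      retstart <- as.integer(param(url, "retstart"))
      retmax <- as.integer(param(url, "retmax"))
      got <- if (retmax > 0 && count > 0) {
        ids[seq.int(retstart + 1, min(count, retstart + retmax))]
      } else character(0)
      paste0("<eSearchResult><Count>", count, "</Count><IdList>",
             paste0("<Id>", got, "</Id>", collapse = ""),
             "</IdList></eSearchResult>")
    } else {
      got <- strsplit(param(url, "id"), ",", fixed = TRUE)[[1]]
      paste(unlist(lapply(got, function(i) {
        c(paste0(">NC_", i, ".1 Xenopus laevis isolate CO1"),
          "ACGTACGTACGTACGTACGT")
      })), collapse = "\n")
    }
  }
}

test_that("NCBI count and fetch parse E-utilities responses", {
  src <- ncbi_source(email = "dev@example.org",
                     transport = fake_ncbi_transport(5),
                     retry_delay = 0)
  src$limiter <- function() NULL
  expect_identical(count_matches(src, "Xenopus laevis", co1), 5L)
  expect_identical(count_matches(src, "Nonexistus fakeus", co1), 0L)
  recs <- fetch_records(src, "Xenopus laevis", co1)
  expect_identical(nrow(recs), 5L)
  expect_identical(recs$source_db, rep("NCBI", 5))
  expect_identical(recs$marker, rep("CO1", 5))
  expect_identical(recs$seq_length, rep(20L, 5))
  expect_match(recs$accession[1], "^NC_90000")
})

test_that("NCBI id search pages through retmax windows", {
  calls <- new.env()
  src <- ncbi_source(email = "dev@example.org",
                     transport = fake_ncbi_transport(7, calls),
                     retry_delay = 0)
  src$limiter <- function() NULL
  ids <- refcov:::ncbi_search_ids(src,
                                  "(\"Xenopus laevis\"[ORGN])",
                                  page_size = 3)
  expect_length(ids, 7)
  expect_identical(length(unique(ids)), 7L)
})

test_that("network failure raises SOURCE_UNAVAILABLE after retries, not zero", {
  boom <- function(url) stop("connection refused")
  src <- ncbi_source(email = "dev@example.org", transport = boom,
                     retries = 3, retry_delay = 0)
  src$limiter <- function() NULL
  expect_error(count_matches(src, "Xenopus laevis", co1),
               class = "refcov_source_unavailable")

  flaky_left <- new.env(); flaky_left$n <- 2L
  ok <- fake_ncbi_transport(2)
  flaky <- function(url) {
    if (flaky_left$n > 0) {
      flaky_left$n <- flaky_left$n - 1L
      stop("transient")
    }
    ok(url)
  }
  src2 <- ncbi_source(email = "dev@example.org", transport = flaky,
                      retries = 5, retry_delay = 0)
  src2$limiter <- function() NULL
  expect_identical(count_matches(src2, "Xenopus laevis", co1), 2L)
})

test_that("the disk cache short-circuits repeated identical requests", {
  calls <- new.env()
  cache <- withr::local_tempdir()
  src <- ncbi_source(email = "dev@example.org",
                     transport = fake_ncbi_transport(4, calls),
                     cache_dir = cache, retry_delay = 0)
  src$limiter <- function() NULL
  expect_identical(count_matches(src, "Xenopus laevis", co1), 4L)
  first <- calls$n
  expect_identical(count_matches(src, "Xenopus laevis", co1), 4L)
  expect_identical(calls$n, first)
})

fake_bold_tsv <- function() {
  hdr <- paste("processid", "genbank_accession", "phylum_name",
               "class_name", "order_name", "family_name", "genus_name",
               "species_name", "markercode", "country", "nucleotides",
               sep = "\t")
  row <- function(pid, gb, sp, mk, cty, seq) {
    paste(pid, gb, "Chordata", "Amphibia", "Anura", "Pipidae", "Xenopus",
          sp, mk, cty, seq, sep = "\t")
  }
  paste(hdr,
        row("BLD001", "KX111.1", "Xenopus laevis", "COI", "Iceland",
            "ACGTACGT"),
        row("BLD002", "", "Xenopus laevis", "COI", "Chile", "ACGTACGTAA"),
        row("BLD003", "", "Xenopus tropicalis", "COI", "", "ACGT"),
        row("BLD004", "", "Xenopus laevis", "16S", "Iceland", "ACGTAC"),
        sep = "\n")
}

test_that("BOLD source maps the combined TSV into records with subtree semantics", {
  src <- bold_source(transport = function(url) fake_bold_tsv(),
                     retry_delay = 0)
  src$limiter <- function() NULL
  expect_identical(count_matches(src, "Xenopus laevis", co1), 2L)
  recs <- fetch_records(src, "Xenopus laevis", co1)
  expect_identical(recs$accession, c("BLD001", "BLD002"))
  expect_identical(recs$genbank_xref, c("KX111.1", NA_character_))
  expect_identical(recs$country, c("Iceland", "Chile"))
  expect_identical(recs$seq_length, c(8L, 10L))
  # genus subtree spans both species
  expect_identical(count_subtree(src, "genus", "Xenopus", co1), 3L)
  # country filter with the reserved Unspecified name
  expect_identical(
    count_subtree(src, "genus", "Xenopus", co1,
                  filter_spec(countries = "Unspecified")), 1L)
})

test_that("genus-level BOLD results contain every member species' records", {
  src <- bold_source(transport = function(url) fake_bold_tsv(),
                     retry_delay = 0)
  src$limiter <- function() NULL
  genus_n <- count_subtree(src, "genus", "Xenopus", co1)
  species_n <- count_matches(src, "Xenopus laevis", co1) +
    count_matches(src, "Xenopus tropicalis", co1)
  expect_true(genus_n >= species_n)
})
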