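test_that("summary matches the hand-enumerated oracle", {
  cells <- matrix(c(5L, 0L, 2L, 1L, 1L, 1L), ncol = 2,
                  dimnames = list(c("a", "b", "c"), c("CO1", "16S")))
  cm <- structure(list(organisms = rownames(cells),
                       barcodes = colnames(cells), cells = cells,
                       fallback_rows = data.frame(), flags = list(),
                       queries = list()),
                  class = "coverage_matrix")
  st <- summary(cm)
  expect_identical(st$n_sequences, c(7L, 3L))
  expect_identical(st$pct_of_total, c(70.0, 30.0))
  expect_identical(st$n_organisms_covered, c(2L, 3L))
  expect_identical(st$n_organisms_missing, c(1L, 0L))
  expect_identical(attr(st, "total_sequences"), 10L)
  expect_identical(attr(st, "total_organisms_detected"), 3L)
})

test_that("all-zero and single-barcode summaries behave at the edges", {
  zero <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("CO1", "16S")))
  cmz <- structure(list(organisms = c("a", "b"), barcodes = c("CO1", "16S"),
                        cells = zero, fallback_rows = data.frame(),
                        flags = list(), queries = list()),
                   class = "coverage_matrix")
  stz <- summary(cmz)
  expect_true(all(stz$pct_of_total == 0))
  expect_true(all(stz$n_organisms_missing == 2L))
  expect_identical(attr(stz, "total_organisms_detected"), 0L)

  one <- matrix(c(3L, 4L), 2, 1, dimnames = list(c("a", "b"), "CO1"))
  cmo <- structure(list(organisms = c("a", "b"), barcodes = "CO1",
                        cells = one, fallback_rows = data.frame(),
                        flags = list(), queries = list()),
                   class = "coverage_matrix")
  expect_identical(summary(cmo)$pct_of_total, 100.0)
})

test_that("summary identities hold on randomized matrices", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n_o <- sample(1:10, 1)
      n_b <- sample(1:5, 1)
      cells <- matrix(sample(0:30, n_o * n_b, replace = TRUE), n_o, n_b,
                      dimnames = list(paste0("org", seq_len(n_o)),
                                      paste0("bc", seq_len(n_b))))
      cm <- structure(list(organisms = rownames(cells),
                           barcodes = colnames(cells), cells = cells,
                           fallback_rows = data.frame(), flags = list(),
                           queries = list()),
                      class = "coverage_matrix")
      st <- summary(cm)
      expect_identical(st$n_sequences, as.integer(colSums(cells)))
      expect_true(all(st$n_organisms_covered + st$n_organisms_missing ==
                        n_o))
      expect_identical(attr(st, "total_sequences"), sum(cells))
      if (sum(cells) > 0) {
        expect_true(abs(sum(st$pct_of_total) - 100) <= 0.5)
      }
    }
  })
})

test_that("length filter keeps inclusive bounds and reports missing-length drops", {
  recs <- as_records(data.frame(
    source_db = "SNAPSHOT", accession = c("a", "b", "c", "d"),
    organism = "X y", marker = "COI",
    seq_length = c(100L, 500L, 900L, NA),
    stringsAsFactors = FALSE))
  out <- apply_length_filter(recs, 200, 800)
  expect_identical(out$accession, "b")
  expect_identical(attr(out, "dropped_missing_length"), 1L)
  # inclusive bounds
  expect_identical(apply_length_filter(recs, 100, 900)$accession,
                   c("a", "b", "c"))
  # no bounds: identity, missing-length records kept
  expect_identical(apply_length_filter(recs)$accession,
                   c("a", "b", "c", "d"))
})

test_that("country filter matches case-insensitively with Unspecified reserved", {
  recs <- as_records(data.frame(
    source_db = "SNAPSHOT", accession = c("a", "b", "c"),
    organism = "X y", marker = "COI",
    country = c("Iceland", "Chile", NA), stringsAsFactors = FALSE))
  expect_identical(apply_country_filter(recs, "iceland")$accession, "a")
  expect_identical(apply_country_filter(recs, "Unspecified")$accession,
                   "c")
  expect_identical(nrow(apply_country_filter(recs, character(0))), 0L)
  expect_identical(apply_country_filter(recs, NULL)$accession,
                   c("a", "b", "c"))
})

test_that("filters agree with a brute-force scan and commute (500 randomized records)", {
  plan <- random_plan(seed = 55, n_organisms = 5, max_count = 25)
  snap <- generate_snapshot(plan)
  recs <- snap$records
  recs$seq_length[seq(1, nrow(recs), by = 13)] <- NA  # absent metadata
  cases <- list(
    list(min = 450, max = 650, cty = NULL),
    list(min = NULL, max = 500, cty = c("Iceland", "Unspecified")),
    list(min = 500, max = NULL, cty = "Japan"),
    list(min = 400, max = 700, cty = c("Canada", "Mexico")))
  for (cs in cases) {
    a <- apply_country_filter(apply_length_filter(recs, cs$min, cs$max),
                              cs$cty)
    b <- apply_length_filter(apply_country_filter(recs, cs$cty),
                             cs$min, cs$max)
    expect_identical(a$accession, b$accession)
    # brute force per organism x marker, summed, equals filtered total
    expected <- 0L
    for (org in unique(recs$organism)) {
      for (syn in unique(recs$marker)) {
        expected <- expected +
          brute_count(recs, org, syn, cs$min, cs$max, cs$cty)
      }
    }
    expect_identical(nrow(a), expected)
  }
})

test_that("cross-database dedupe removes exactly the mirrored records", {
  plan <- random_plan(seed = 21, n_organisms = 4, max_count = 6)
  plan$overlap_k <- 4L
  pair <- generate_pair(plan)
  dd <- dedupe_cross_db(pair$bold$records, pair$ncbi$records$accession)
  expect_identical(nrow(dd$removed), 4L)
  expect_identical(nrow(dd$kept) + nrow(dd$removed),
                   nrow(pair$bold$records))
  strip <- function(x) sub("\\.[0-9]+$", "", x)
  left <- strip(dd$kept$genbank_xref)
  expect_length(intersect(left[!is.na(left)],
                          pair$ncbi$records$accession), 0)
  # absent xref is always kept; empty NCBI set is identity
  expect_identical(nrow(dedupe_cross_db(pair$bold$records,
                                        character(0))$removed), 0L)
})

test_that("country tally aggregates with Unspecified for absent metadata", {
  recs <- as_records(data.frame(
    source_db = "SNAPSHOT", accession = letters[1:5],
    organism = c("A a", "A a", "B b", "B b", "C c"), marker = "COI",
    country = c("Iceland", "Iceland", "Chile", NA, NA),
    stringsAsFactors = FALSE))
  t <- country_tally(recs)
  expect_identical(t$country, c("Iceland", "Unspecified", "Chile"))
  expect_identical(t$n_records, c(2L, 2L, 1L))
  expect_identical(t$n_organisms, c(1L, 2L, 1L))
  expect_identical(sum(t$n_records), nrow(recs))
  expect_identical(nrow(country_tally(empty_records())), 0L)
})

test_that("coverage matrix flags source errors as NA cells, never zero", {
  cm <- build_coverage_matrix(failing_source(), "X y", co1)
  expect_true(is.na(cm$cells[1, 1]))
  expect_identical(cm$flags[["X y"]], "SOURCE_ERROR")
})

test_that("unregistered organisms keep an all-zero row with flag and no fallback rows", {
  snap <- tiny_snapshot()
  cm <- build_coverage_matrix(snap, "Euwallacea whitfordiodendrus",
                              list(co1, s16), enable_fallback = TRUE)
  expect_identical(unname(cm$cells[1, ]), c(0L, 0L))
  expect_identical(cm$flags[[1]], "UNREGISTERED")
  expect_identical(nrow(cm$fallback_rows), 0L)
})

test_that("fallback rows populate beneath zero cells", {
  snap <- tiny_snapshot()
  cm <- build_coverage_matrix(snap, c("Xenopus borealis"), co1,
                              enable_fallback = TRUE)
  expect_identical(unname(cm$cells[1, 1]), 0L)
  fb <- cm$fallback_rows
  expect_identical(fb$rank, c("genus", "family", "order"))
  expect_identical(fb$count, c(7L, 7L, 7L))
})

test_that("corrected names pool into the input organism's row", {
  snap <- tiny_snapshot()
  tbl <- data.frame(wrong_name = "Xenopus laeviss",
                    correct_name = "Xenopus laevis")
  qs <- resolve_names("Xenopus laeviss", table_resolver(tbl))
  cm <- build_coverage_matrix(snap, qs, co1)
  expect_identical(unname(cm$cells[1, 1]), 3L)
  expect_identical(cm$organisms, "Xenopus laeviss")
  expect_true("CORRECTED" %in% cm$flags[[1]])
})
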