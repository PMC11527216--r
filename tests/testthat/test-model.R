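test_that("normalize_marker maps synonyms to canonical names", {
  expect_identical(normalize_marker("COI"), "CO1")
  expect_identical(normalize_marker("CO1"), "CO1")
  expect_identical(normalize_marker("rbcL"), NA_character_)
  expect_identical(normalize_marker("  coi "), "CO1")
  expect_identical(normalize_marker("Vert12S"), "12S")
  # exact match, not substring
  expect_identical(normalize_marker("CO12"), NA_character_)
})

test_that("normalize_marker is idempotent on matched labels", {
  labels <- unlist(lapply(default_barcode_groups(), `[[`, "synonyms"))
  once <- normalize_marker(labels)
  expect_false(anyNA(once))
  expect_identical(normalize_marker(once), once)
})

test_that("default groups have disjoint synonym sets", {
  groups <- default_barcode_groups()
  syn <- tolower(unlist(lapply(groups, `[[`, "synonyms")))
  expect_identical(anyDuplicated(syn), 0L)
  # and the loader enforces it
  bad <- list(barcode_group("A", "X"), barcode_group("B", "x"))
  expect_error(normalize_marker("X", bad),
               class = "refcov_overlapping_groups")
})

test_that("validate_record flags each broken invariant by field", {
  ok <- sequence_record("SNAPSHOT", "A1", "Xenopus laevis", "COI",
                        sequence = "ACGT")
  expect_identical(validate_record(ok), character(0))
  expect_identical(ok$seq_length, 4L)

  bad_len <- sequence_record("SNAPSHOT", "A1", "Xenopus laevis", "COI",
                             sequence = "ACGT", seq_length = 7L)
  v <- validate_record(bad_len)
  expect_length(v, 1)
  expect_match(v, "^seq_length")

  no_acc <- sequence_record("SNAPSHOT", "", "Xenopus laevis", "COI",
                            sequence = "ACGT")
  expect_match(validate_record(no_acc), "^accession")

  # gaps excluded from the length check
  gapped <- sequence_record("SNAPSHOT", "A2", "Xenopus laevis", "COI",
                            sequence = "AC-GT", seq_length = 4L)
  expect_identical(validate_record(gapped), character(0))

  xref <- sequence_record("NCBI", "A3", "Xenopus laevis", "COI",
                          sequence = "ACGT", genbank_xref = "KX123")
  expect_match(validate_record(xref), "^genbank_xref")
  xref_bold <- sequence_record("BOLD", "A3", "Xenopus laevis", "COI",
                               sequence = "ACGT", genbank_xref = "KX123")
  expect_identical(validate_record(xref_bold), character(0))

  alien <- sequence_record("SNAPSHOT", "A4", "Xenopus laevis", "COI",
                           sequence = "ACGTZ")
  expect_match(validate_record(alien), "^sequence")
})

test_that("lineage strings round-trip through parse/make", {
  lin <- make_lineage(superkingdom = "Eukaryota", order = "Anura",
                      family = "Pipidae", genus = "Xenopus",
                      species = "Xenopus laevis")
  p <- parse_lineage(lin)
  expect_identical(p[["species"]], "Xenopus laevis")
  expect_identical(p[["genus"]], "Xenopus")
  expect_true(is.na(p[["phylum"]]))
  expect_identical(unname(parse_lineage(NA_character_)),
                   rep(NA_character_, 7))
  expect_error(make_lineage(kingdom = "x"), class = "refcov_bad_lineage")
})

test_that("filter_spec validates bounds", {
  expect_error(filter_spec(min_length = 500, max_length = 100),
               class = "refcov_bad_filter")
  f <- filter_spec(min_length = 100, max_length = 500)
  expect_identical(f$min_length, 100)
})

test_that("organism_query keeps the input first and deduplicates", {
  q <- organism_query("Xenopus laeviss",
                      c("Xenopus laevis", "Xenopus laeviss"))
  expect_identical(q$resolved_names[1], "Xenopus laeviss")
  expect_identical(q$resolved_names,
                   c("Xenopus laeviss", "Xenopus laevis"))
})

test_that("groups_for_barcodes resolves labels or builds singletons", {
  gs <- groups_for_barcodes(c("COI", "rbcL", "CO1"))
  expect_identical(names(gs), c("CO1", "rbcL"))
  expect_true(length(gs$CO1$synonyms) > 1)
  expect_identical(gs$rbcL$synonyms, "rbcL")
})
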