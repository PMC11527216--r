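test_that("resolve_names appends corrections, never replaces", {
  qs <- resolve_names("Xenopus laevis")
  expect_identical(qs[[1]]$resolved_names, "Xenopus laevis")
  expect_identical(nrow(qs[[1]]$resolution_log), 0L)

  tbl <- data.frame(wrong_name = "Xenopus laeviss",
                    correct_name = "Xenopus laevis",
                    stringsAsFactors = FALSE)
  qs <- resolve_names(c("Xenopus laeviss", "Xenopus laevis"),
                      table_resolver(tbl))
  expect_identical(qs[[1]]$resolved_names,
                   c("Xenopus laeviss", "Xenopus laevis"))
  expect_identical(nrow(qs[[1]]$resolution_log), 1L)
  # correction equal to the input is not appended
  expect_identical(qs[[2]]$resolved_names, "Xenopus laevis")
})

test_that("a failing resolver degrades to identity with a warning", {
  boom <- function(name) stop("resolver exploded")
  qs <- NULL
  expect_warning(qs <- resolve_names("Xenopus laevis", boom),
                 class = "refcov_resolver_failure")
  expect_identical(qs[[1]]$resolved_names, "Xenopus laevis")
})

test_that("lineage_of answers from the backbone or NULL for unregistered names", {
  snap <- tiny_snapshot()
  lin <- lineage_of("Xenopus laevis", snap)
  expect_identical(lin[["genus"]], "Xenopus")
  expect_identical(lin[["order"]], "Anura")
  expect_null(lineage_of("Euwallacea whitfordiodendrus", snap))
})

test_that("fallback stops at species when the count is positive", {
  snap <- tiny_snapshot()
  fs <- fallback_search(snap, "Xenopus laevis", co1, snap$backbone)
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$count, 3L)
  log <- attr(fs, "query_log")
  expect_true(all(log$rank == "species"))
})

test_that("fallback reports genus, family and order when species is empty", {
  snap <- tiny_snapshot()
  # borealis is registered with no records; congeners have 7 CO1 records
  fs <- fallback_search(snap, "Xenopus borealis", co1, snap$backbone)
  expect_identical(fs$rank, c("species", "genus", "family", "order"))
  expect_identical(fs$count, c(0L, 7L, 7L, 7L))
  expect_false(attr(fs, "unregistered"))
})

test_that("fallback counts are monotone along the rank ladder", {
  plan <- random_plan(seed = 41, n_organisms = 8, max_count = 5)
  snap <- generate_snapshot(plan)
  gs <- groups_for_barcodes(plan$barcodes)
  for (seed_org in plan$organisms$binomial) {
    for (g in gs) {
      if (count_matches(snap, seed_org, g) > 0) next
      fs <- fallback_search(snap, seed_org, g, snap$backbone)
      anc <- fs$count[match(c("genus", "family", "order"), fs$rank)]
      anc <- anc[!is.na(anc)]
      expect_true(all(diff(anc) >= 0))
    }
  }
})

test_that("unregistered species get a zero row, a flag, and no ancestor queries", {
  snap <- tiny_snapshot()
  fs <- fallback_search(snap, "Euwallacea whitfordiodendrus", co1,
                        snap$backbone)
  expect_identical(nrow(fs), 1L)
  expect_identical(fs$count, 0L)
  expect_true(attr(fs, "unregistered"))
  log <- attr(fs, "query_log")
  expect_true(all(log$rank == "species"))
})

test_that("a moved species walks the backbone genus with a drift warning", {
  recs <- make_recs(4, "Aquarana clamitans", "COI")
  backbone <- data.frame(
    name = c("Lithobates catesbeianus", "Aquarana clamitans"),
    lineage = c(
      "Eukaryota;Chordata;Amphibia;Anura;Ranidae;Aquarana;Lithobates catesbeianus",
      "Eukaryota;Chordata;Amphibia;Anura;Ranidae;Aquarana;Aquarana clamitans"),
    stringsAsFactors = FALSE)
  snap <- snapshot_source(recs, backbone)
  fs <- NULL
  expect_warning(
    fs <- fallback_search(snap, "Lithobates catesbeianus", co1,
                          snap$backbone),
    class = "refcov_taxonomy_drift")
  expect_identical(fs$taxon[fs$rank == "genus"], "Aquarana")
  expect_identical(fs$count[fs$rank == "genus"], 4L)
})
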