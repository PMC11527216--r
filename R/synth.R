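# Synthetic snapshot generator. A CoveragePlan states the world —
# organisms with lineages, barcodes, a planted count per
# organism-barcode pair, country pool, length range, seed — and the
# generator realizes exactly that world, so the planted plan is the
# oracle for everything downstream (coverage recovery, dedupe counts,
# filter scans).

#' Specify a coverage plan for the synthetic generator
#'
#' @param organisms Either a character vector of binomials (genus taken
#'   from the first word; family/order synthesized from it) or a
#'   data.frame with columns `binomial`, `genus`, `family`, `order` and
#'   optionally `registered` (default `TRUE`; unregistered organisms
#'   are omitted from the generated taxonomy backbone).
#' @param barcodes Character vector of canonical barcode names.
#' @param counts Planted records per pair: an organisms x barcodes
#'   integer matrix, or a long data.frame with columns `organism`,
#'   `barcode`, `count`. Every pair must be covered.
#' @param seed Integer seed; identical seeds give identical snapshots,
#'   distinct seeds give distinct accession sets.
#' @param overlap_k For [generate_pair()]: how many BOLD records carry
#'   a GenBank cross-reference planted in the NCBI-like snapshot.
#' @param country_pool Countries sampled for record metadata.
#' @param country_weights Sampling weights (default uniform).
#' @param p_country_missing Probability a record has no recorded
#'   country (databases hold entries with incomplete metadata).
#' @param length_range Inclusive sequence-length range in nucleotides;
#'   the default 400-700 spans typical barcode amplicons.
#' @return An object of class `coverage_plan`.
#' @export
coverage_plan <- function(organisms, barcodes, counts, seed = 1L,
                          overlap_k = 0L,
                          country_pool = c("United States", "Canada",
                                           "Mexico", "Japan", "Iceland"),
                          country_weights = NULL,
                          p_country_missing = 0.2,
                          length_range = c(400L, 700L)) {
  if (is.character(organisms)) {
    genus <- vapply(strsplit(organisms, " ", fixed = TRUE), `[[`,
                    character(1), 1L)
    organisms <- data.frame(binomial = organisms, genus = genus,
                            family = paste0(genus, "idae"),
                            order = paste0(genus, "iformes"),
                            registered = TRUE, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("binomial", "genus", "family", "order") %in%
                  names(organisms)))
  if (!"registered" %in% names(organisms)) organisms$registered <- TRUE
  barcodes <- as.character(barcodes)
  if (is.data.frame(counts)) {
    stopifnot(all(c("organism", "barcode", "count") %in% names(counts)))
    mat <- matrix(NA_integer_, nrow = nrow(organisms),
                  ncol = length(barcodes),
                  dimnames = list(organisms$binomial, barcodes))
    for (i in seq_len(nrow(counts))) {
      mat[counts$organism[i], counts$barcode[i]] <-
        as.integer(counts$count[i])
    }
    counts <- mat
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(organisms) || ncol(counts) != length(barcodes) ||
      anyNA(counts)) {
    rc_abort("invalid_plan",
             "counts must cover every organism x barcode pair")
  }
  if (any(counts < 0)) rc_abort("invalid_plan", "counts must be >= 0")
  dimnames(counts) <- list(organisms$binomial, barcodes)
  if (overlap_k < 0) rc_abort("invalid_plan", "overlap_k must be >= 0")
  if (overlap_k > sum(counts)) {
    rc_abort("invalid_plan",
             "overlap_k exceeds the total number of planted records")
  }
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            length_range[1] >= 1)
  structure(list(organisms = organisms, barcodes = barcodes,
                 counts = counts, seed = as.integer(seed),
                 overlap_k = as.integer(overlap_k),
                 country_pool = country_pool,
                 country_weights = country_weights,
                 p_country_missing = p_country_missing,
                 length_range = as.integer(length_range)),
            class = "coverage_plan")
}

#' A random coverage plan
#'
#' The shape used throughout the test suite: 8 organisms (two species
#' per genus, so genus-fallback has congeners to find) x 4 barcodes,
#' planted counts uniform on 0..20.
#'
#' @param seed Integer seed.
#' @param n_organisms,barcodes,max_count Plan shape knobs.
#' @return A `coverage_plan`.
#' @export
random_plan <- function(seed, n_organisms = 8,
                        barcodes = c("CO1", "16S", "18S", "12S"),
                        max_count = 20) {
  withr::with_seed(seed, {
    n_gen <- max(1L, ceiling(n_organisms / 2))
    genera <- sprintf("Synthogenus%s", LETTERS[seq_len(n_gen)])
    genus <- rep_len(genera, n_organisms)
    binomial <- sprintf("%s species%02d", genus, seq_len(n_organisms))
    fams <- sprintf("Synthofam%s", LETTERS[seq_len(max(1L, ceiling(n_gen / 2)))])
    family <- rep_len(fams, n_gen)[match(genus, genera)]
    organisms <- data.frame(
      binomial = binomial, genus = genus, family = family,
      order = "Synthorder", registered = TRUE, stringsAsFactors = FALSE)
    counts <- matrix(sample(0:max_count, n_organisms * length(barcodes),
                            replace = TRUE),
                     nrow = n_organisms,
                     dimnames = list(binomial, barcodes))
    coverage_plan(organisms, barcodes, counts, seed = seed)
  })
}

plan_lineage <- function(org_row) {
  make_lineage(superkingdom = "Eukaryota", order = org_row$order,
               family = org_row$family, genus = org_row$genus,
               species = org_row$binomial)
}

#' Generate a snapshot realizing a coverage plan
#'
#' Exactly `counts[o, b]` records per organism-barcode pair. Marker
#' labels cycle through each barcode group's synonym spellings so that
#' marker normalization is exercised, sequences are seeded-random over
#' A/C/G/T with lengths uniform in the plan's range (the audited
#' keyword predicate never reads sequence content, so compositional
#' realism is irrelevant), and countries are drawn from the plan's pool
#' with some records left unrecorded. Unregistered organisms are
#' omitted from the backbone. Identical plans give identical snapshots.
#'
#' @param plan A [coverage_plan()].
#' @param source_db Source label stamped on the records.
#' @param accession_prefix Accession prefix (synthetic-style ids,
#'   never colliding with real ones).
#' @param groups Barcode groups supplying synonym spellings.
#' @return A [snapshot_source()].
#' @export
generate_snapshot <- function(plan, source_db = "SNAPSHOT",
                              accession_prefix = "SYN",
                              groups = default_barcode_groups()) {
  stopifnot(inherits(plan, "coverage_plan"))
  glist <- groups_for_barcodes(plan$barcodes, groups)
  withr::with_seed(plan$seed, {
    rows <- list()
    counter <- 0L
    tag <- plan$seed %% 65536L
    for (i in seq_len(nrow(plan$organisms))) {
      org <- plan$organisms[i, ]
      lineage <- plan_lineage(org)
      for (b in plan$barcodes) {
        k <- plan$counts[i, b]
        if (k == 0L) next
        syns <- glist[[normalize_marker(b, glist)]]$synonyms
        for (j in seq_len(k)) {
          counter <- counter + 1L
          len <- sample(seq.int(plan$length_range[1], plan$length_range[2]),
                        1L)
          country <- if (stats::runif(1) < plan$p_country_missing) {
            NA_character_
          } else {
            sample(plan$country_pool, 1L, prob = plan$country_weights)
          }
          rows[[counter]] <- data.frame(
            source_db = source_db,
            accession = sprintf("%s%05d%05d", accession_prefix, tag,
                                counter),
            organism = org$binomial, lineage = lineage,
            marker = syns[(j - 1L) %% length(syns) + 1L],
            seq_length = len, country = country,
            genbank_xref = NA_character_,
            sequence = paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
    recs <- if (counter > 0) as_records(do.call(rbind, rows)) else
      empty_records()
    reg <- plan$organisms[plan$organisms$registered, , drop = FALSE]
    backbone <- if (nrow(reg) > 0) {
      data.frame(name = reg$binomial,
                 lineage = vapply(seq_len(nrow(reg)), function(i) {
                   plan_lineage(reg[i, ])
                 }, character(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    snapshot_source(recs, backbone, seed = plan$seed)
  })
}

#' Generate an NCBI-like / BOLD-like snapshot pair with planted overlap
#'
#' The BOLD-like snapshot has exactly `plan$overlap_k` records whose
#' `genbank_xref` (with a version suffix, exercising version
#' stripping) matches an accession present in the NCBI-like snapshot;
#' every other cross-reference is absent. The plan's `overlap_k` is the
#' oracle for [dedupe_cross_db()].
#'
#' @param plan A [coverage_plan()]; `overlap_k` must not exceed the
#'   total planted BOLD records.
#' @return A list with `ncbi` and `bold` [snapshot_source()]s.
#' @export
generate_pair <- function(plan) {
  stopifnot(inherits(plan, "coverage_plan"))
  ncbi <- generate_snapshot(plan, source_db = "NCBI",
                            accession_prefix = "SNCB")
  bold_plan <- plan
  bold_plan$seed <- plan$seed + 1L
  bold <- generate_snapshot(bold_plan, source_db = "BOLD",
                            accession_prefix = "SBLD")
  k <- plan$overlap_k
  if (k > nrow(bold$records)) {
    rc_abort("invalid_plan",
             sprintf("overlap_k (%d) exceeds planted BOLD records (%d)",
                     k, nrow(bold$records)))
  }
  if (k > 0) {
    withr::with_seed(plan$seed + 2L, {
      bold_idx <- sample(nrow(bold$records), k)
      ncbi_acc <- sample(ncbi$records$accession, k)
      bold$records$genbank_xref[bold_idx] <- paste0(ncbi_acc, ".1")
    })
  }
  list(ncbi = ncbi, bold = bold)
}

## ---- plan serialization ----------------------------------------------

#' Write a coverage plan to CSV
#'
#' One row per organism x barcode count, preceded by `#`-comment
#' key-value config lines (seed, overlap and sampling knobs).
#'
#' @param plan A [coverage_plan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, path) {
  hdr <- c(
    sprintf("# seed=%d", plan$seed),
    sprintf("# overlap_k=%d", plan$overlap_k),
    sprintf("# length_range=%d,%d", plan$length_range[1],
            plan$length_range[2]),
    sprintf("# country_pool=%s", paste(plan$country_pool, collapse = "|")),
    sprintf("# p_country_missing=%g", plan$p_country_missing))
  rows <- list(c("organism", "genus", "family", "order", "registered",
                 "barcode", "count"))
  for (i in seq_len(nrow(plan$organisms))) {
    org <- plan$organisms[i, ]
    for (b in plan$barcodes) {
      rows[[length(rows) + 1]] <- c(
        org$binomial, org$genus, org$family, org$order,
        tolower(as.character(org$registered)), b, plan$counts[i, b])
    }
  }
  body <- vapply(rows, function(r) paste(csv_field(r), collapse = ","),
                 character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(c(hdr, body), collapse = "\n"), "\n"), con,
            eos = NULL, useBytes = TRUE)
  invisible(path)
}

#' Read a coverage plan from CSV
#'
#' @param path A CSV written by [write_plan_csv()] (or hand-authored in
#'   the same layout).
#' @param seed Optional seed overriding the file's `# seed=` config.
#' @return A [coverage_plan()].
#' @export
read_plan_csv <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  cfg_lines <- grep("^#", lines, value = TRUE)
  cfg <- list()
  for (l in cfg_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) cfg[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, value = TRUE,
                                          invert = TRUE), collapse = "\n"),
                        colClasses = "character")
  need <- c("organism", "barcode", "count")
  if (!all(need %in% names(df))) {
    rc_abort("invalid_plan",
             sprintf("%s: plan CSV needs columns %s", path,
                     paste(need, collapse = ",")))
  }
  orgs <- df[!duplicated(df$organism),
             intersect(c("organism", "genus", "family", "order",
                         "registered"), names(df)), drop = FALSE]
  organisms <- data.frame(
    binomial = orgs$organism,
    genus = orgs$genus %||% vapply(strsplit(orgs$organism, " "), `[[`,
                                   character(1), 1L),
    family = orgs$family %||% NA_character_,
    order = orgs$order %||% NA_character_,
    registered = if ("registered" %in% names(orgs)) {
      tolower(orgs$registered) %in% c("true", "t", "1", "yes")
    } else TRUE,
    stringsAsFactors = FALSE)
  barcodes <- unique(df$barcode)
  counts <- data.frame(organism = df$organism, barcode = df$barcode,
                       count = as.integer(df$count),
                       stringsAsFactors = FALSE)
  lr <- if (!is.null(cfg$length_range)) {
    as.integer(strsplit(cfg$length_range, ",", fixed = TRUE)[[1]])
  } else c(400L, 700L)
  coverage_plan(
    organisms, barcodes, counts,
    seed = as.integer(seed %||% cfg$seed %||% 1L),
    overlap_k = as.integer(cfg$overlap_k %||% 0L),
    country_pool = if (!is.null(cfg$country_pool)) {
      strsplit(cfg$country_pool, "|", fixed = TRUE)[[1]]
    } else c("United States", "Canada", "Mexico", "Japan", "Iceland"),
    p_country_missing = as.numeric(cfg$p_country_missing %||% 0.2),
    length_range = lr)
}

#' The bundled demo plan
#'
#' Emulates the coverage-gap structure of a CRUX-style audit of 11
#' invasive California species: CO1 has coverage for five of them, 16S
#' for six, other loci are empty; *Euwallacea whitfordiodendrus* is
#' left unregistered in the backbone (so its row stays all-zero with no
#' broader search), *Lithobates catesbeianus* sits under backbone genus
#' *Aquarana* (a moved species), and two background congeners carry the
#' records that genus-level fallback should find. Lineages are
#' synthetic stand-ins shaped like real ones, not authoritative
#' taxonomy.
#'
#' @param seed Integer seed.
#' @return A `coverage_plan`.
#' @export
demo_plan <- function(seed = 20240101L) {
  organisms <- data.frame(
    binomial = c("Eleutherodactylus coqui", "Lithobates catesbeianus",
                 "Xenopus laevis", "Ctenopharyngodon idella",
                 "Dreissena polymorpha", "Dreissena bugensis",
                 "Eriocheir senensis", "Euwallacea kuroshio",
                 "Euwallacea whitfordiodendrus", "Pomacea canaliculata",
                 "Potamopyrgus antipodarum",
                 # background congeners, not part of the demo query
                 "Aquarana clamitans", "Euwallacea validus"),
    genus = c("Eleutherodactylus", "Aquarana", "Xenopus",
              "Ctenopharyngodon", "Dreissena", "Dreissena", "Eriocheir",
              "Euwallacea", "Euwallacea", "Pomacea", "Potamopyrgus",
              "Aquarana", "Euwallacea"),
    family = c("Eleutherodactylidae", "Ranidae", "Pipidae",
               "Xenocyprididae", "Dreissenidae", "Dreissenidae",
               "Varunidae", "Curculionidae", "Curculionidae",
               "Ampullariidae", "Tateidae", "Ranidae", "Curculionidae"),
    order = c("Anura", "Anura", "Anura", "Cypriniformes", "Myida",
              "Myida", "Decapoda", "Coleoptera", "Coleoptera",
              "Architaenioglossa", "Littorinimorpha", "Anura",
              "Coleoptera"),
    registered = c(rep(TRUE, 8), FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  barcodes <- c("CO1", "16S", "18S", "12S", "FITS", "PITS", "trnL")
  counts <- matrix(0L, nrow = nrow(organisms), ncol = length(barcodes),
                   dimnames = list(organisms$binomial, barcodes))
  counts[c("Eleutherodactylus coqui", "Xenopus laevis",
           "Ctenopharyngodon idella", "Pomacea canaliculata",
           "Potamopyrgus antipodarum"), "CO1"] <- c(31L, 38L, 12L, 9L, 7L)
  counts[c("Eleutherodactylus coqui", "Xenopus laevis",
           "Ctenopharyngodon idella", "Pomacea canaliculata",
           "Potamopyrgus antipodarum", "Lithobates catesbeianus"),
         "16S"] <- c(2L, 3L, 2L, 1L, 1L, 3L)
  counts["Aquarana clamitans", "CO1"] <- 5L
  counts["Euwallacea validus", "CO1"] <- 4L
  coverage_plan(organisms, barcodes, counts, seed = seed)
}
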