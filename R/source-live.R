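# Live record sources: NCBI Nucleotide via the Entrez E-utilities
# (two-phase search-then-fetch with retmax paging and batched efetch)
# and the BOLD public combined specimen+sequence API. Both take an
# injectable `transport` function (url -> response text) so the full
# code path is exercisable offline with canned responses, and an
# optional on-disk response cache keyed by request URL — iterative
# re-searching is the dominant use pattern, so repeated queries should
# not re-hit the endpoints.

#' Default HTTP transport
#'
#' @param timeout Seconds before a request is abandoned.
#' @return A function `url -> response text` used by the live sources;
#'   replace it with a test double to run the live code paths offline.
#' @export
http_transport <- function(timeout = 30) {
  force(timeout)
  function(url) {
    con <- base::url(url)
    on.exit(close(con))
    old <- options(timeout = timeout)
    on.exit(options(old), add = TRUE)
    paste(readLines(con, warn = FALSE), collapse = "\n")
  }
}

# Exponential backoff around a transport call; after `retries` failed
# attempts raises SOURCE_UNAVAILABLE (never returned as a zero count).
with_retries <- function(fun, retries = 5, base_delay = 0.5,
                         what = "request") {
  last <- NULL
  for (attempt in seq_len(max(1L, retries))) {
    out <- tryCatch(fun(), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last <- out
    if (attempt < retries) Sys.sleep(base_delay * 2^(attempt - 1))
  }
  rc_abort("source_unavailable",
           sprintf("%s failed after %d attempts: %s", what, retries,
                   conditionMessage(last)))
}

# Token-interval rate limiter (E-utilities policy: 3 req/s without an
# API key, 10/s with one).
make_rate_limiter <- function(rps) {
  env <- new.env(parent = emptyenv())
  env$last <- -Inf
  function() {
    gap <- 1 / rps
    now <- as.numeric(Sys.time())
    wait <- env$last + gap - now
    if (wait > 0) Sys.sleep(wait)
    env$last <- as.numeric(Sys.time())
    invisible(NULL)
  }
}

cache_key <- function(text) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(text, tmp)
  unname(tools::md5sum(tmp))
}

# One transport call with caching + retries + rate limiting.
live_request <- function(src, url, bypass_cache = FALSE) {
  cpath <- NULL
  if (!is.null(src$cache_dir)) {
    dir.create(src$cache_dir, showWarnings = FALSE, recursive = TRUE)
    cpath <- file.path(src$cache_dir,
                       paste0(src$db_tag, "-", cache_key(url), ".txt"))
    if (!bypass_cache && file.exists(cpath)) {
      return(readChar(cpath, file.info(cpath)$size, useBytes = TRUE))
    }
  }
  src$limiter()
  txt <- with_retries(function() src$transport(url), retries = src$retries,
                      base_delay = src$retry_delay, what = url)
  if (!is.null(cpath)) {
    con <- file(cpath, "wb")
    writeChar(txt, con, eos = NULL, useBytes = TRUE)
    close(con)
  }
  txt
}

## ---- NCBI ------------------------------------------------------------

#' Live NCBI Nucleotide source (Entrez E-utilities)
#'
#' Two-phase access: `esearch` for counts and id lists (with `retmax`
#' paging), then batched `efetch` of at most 200 ids per request for
#' sequences. Requests are rate-limited to 3/s without an API key and
#' 10/s with one, retried with exponential backoff, and optionally
#' cached on disk.
#'
#' @param email Contact email (E-utilities usage policy; required for
#'   live runs).
#' @param api_key Optional NCBI API key.
#' @param base_url E-utilities base URL; point at a test double to run
#'   offline.
#' @param transport Function `url -> response text` (see
#'   [http_transport()]).
#' @param cache_dir Directory for the on-disk response cache, or `NULL`
#'   to disable caching.
#' @param retries Attempts per request before `SOURCE_UNAVAILABLE`.
#' @param retry_delay Base backoff delay in seconds.
#' @param mode Entrez term mode, `"fielded"` (`[ORGN]`/`[GENE]`) or
#'   `"all_fields"` for records with incomplete gene metadata.
#' @return An object of class `ncbi_source`.
#' @export
ncbi_source <- function(email = NULL, api_key = NULL,
                        base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils",
                        transport = http_transport(),
                        cache_dir = NULL, retries = 5, retry_delay = 0.5,
                        mode = c("fielded", "all_fields")) {
  mode <- match.arg(mode)
  rps <- if (is.null(api_key)) 3 else 10
  structure(list(email = email, api_key = api_key, base_url = base_url,
                 transport = transport, cache_dir = cache_dir,
                 retries = retries, retry_delay = retry_delay,
                 mode = mode, db_tag = "ncbi",
                 limiter = make_rate_limiter(rps)),
            class = c("ncbi_source", "record_source"))
}

#' @export
source_name.ncbi_source <- function(src) "ncbi"

#' @export
source_capabilities.ncbi_source <- function(src) {
  c("COUNT", "FETCH", "SUBTREE_QUERY", "GENBANK")
}

ncbi_url <- function(src, endpoint, params) {
  extra <- c(
    if (!is.null(src$email)) paste0("email=", utils::URLencode(src$email, reserved = TRUE)),
    if (!is.null(src$api_key)) paste0("api_key=", src$api_key)
  )
  paste0(src$base_url, "/", endpoint, ".fcgi?",
         paste(c(params, extra), collapse = "&"))
}

ncbi_esearch <- function(src, term, retstart = 0, retmax = 0) {
  url <- ncbi_url(src, "esearch", c(
    "db=nuccore",
    paste0("term=", utils::URLencode(term, reserved = TRUE)),
    paste0("retstart=", retstart),
    paste0("retmax=", retmax)))
  xml2::read_xml(live_request(src, url))
}

#' @export
count_matches.ncbi_source <- function(src, organism, group,
                                      filters = filter_spec()) {
  stmt <- build_entrez_term(organism, group, mode = src$mode,
                            filters = filters)
  doc <- ncbi_esearch(src, stmt$text)
  as.integer(xml2::xml_text(xml2::xml_find_first(doc, "//Count")))
}

ncbi_search_ids <- function(src, term, page_size = 500) {
  ids <- character(0)
  start <- 0
  repeat {
    doc <- ncbi_esearch(src, term, retstart = start, retmax = page_size)
    total <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "//Count")))
    batch <- xml2::xml_text(xml2::xml_find_all(doc, "//IdList/Id"))
    ids <- c(ids, batch)
    start <- start + length(batch)
    if (start >= total || length(batch) == 0) break
  }
  ids
}

parse_fasta_text <- function(txt) {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  seqs <- Biostrings::readDNAStringSet(tmp)
  data.frame(
    accession = vapply(strsplit(names(seqs), "[[:space:]]+"), `[[`,
                       character(1), 1L),
    description = names(seqs),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
}

#' @export
fetch_records.ncbi_source <- function(src, organism, group,
                                      filters = filter_spec(),
                                      want_sequence = TRUE) {
  stmt <- build_entrez_term(organism, group, mode = src$mode,
                            filters = filters)
  ids <- ncbi_search_ids(src, stmt$text)
  if (length(ids) == 0) return(empty_records())
  batches <- split(ids, ceiling(seq_along(ids) / 200))
  parts <- list()
  failed <- character(0)
  for (b in batches) {
    url <- ncbi_url(src, "efetch", c(
      "db=nuccore", paste0("id=", paste(b, collapse = ",")),
      "rettype=fasta", "retmode=text"))
    txt <- tryCatch(live_request(src, url),
                    refcov_source_unavailable = function(e) e)
    if (inherits(txt, "condition")) {
      failed <- c(failed, conditionMessage(txt))
      next
    }
    parts[[length(parts) + 1]] <- parse_fasta_text(txt)
  }
  fa <- if (length(parts) > 0) do.call(rbind, parts) else
    data.frame(accession = character(0), description = character(0),
               sequence = character(0), stringsAsFactors = FALSE)
  # server order preserved; duplicates within a response tie-broken by
  # accession
  recs <- as_records(data.frame(
    source_db = "NCBI", accession = fa$accession, organism = organism,
    lineage = NA_character_, marker = group$canonical,
    seq_length = nchar(gsub("-", "", fa$sequence, fixed = TRUE)),
    country = NA_character_, genbank_xref = NA_character_,
    sequence = if (want_sequence) fa$sequence else NA_character_,
    stringsAsFactors = FALSE))
  if (length(failed) > 0) {
    attr(recs, "errors") <- failed
    rc_warn("partial_fetch",
            sprintf("%d of %d efetch batches failed; returning partial results",
                    length(failed), length(batches)))
  }
  recs
}

#' @export
count_subtree.ncbi_source <- function(src, rank, taxon, group,
                                      filters = filter_spec()) {
  # Entrez expands [ORGN] terms over the taxonomic subtree
  count_matches(src, taxon, group, filters)
}

## ---- BOLD ------------------------------------------------------------

#' Live BOLD source (public combined API)
#'
#' Retrieves specimen+sequence TSVs per taxon; BOLD resolves taxa with
#' subtree semantics server-side, so a genus query returns records for
#' every species beneath it. The `processid`, `genbank_accession`,
#' `species_name`, `markercode`, `nucleotides` and `country` fields map
#' into the record table; the GenBank cross-reference enables
#' deduplication against NCBI ([dedupe_cross_db()]).
#'
#' @param base_url Combined-API base URL; point at a test double to run
#'   offline.
#' @inheritParams ncbi_source
#' @return An object of class `bold_source`.
#' @export
bold_source <- function(base_url = "https://v4.boldsystems.org/index.php/API_Public/combined",
                        transport = http_transport(), cache_dir = NULL,
                        retries = 5, retry_delay = 0.5) {
  structure(list(base_url = base_url, transport = transport,
                 cache_dir = cache_dir, retries = retries,
                 retry_delay = retry_delay, db_tag = "bold",
                 limiter = make_rate_limiter(3)),
            class = c("bold_source", "record_source"))
}

#' @export
source_name.bold_source <- function(src) "bold"

#' @export
source_capabilities.bold_source <- function(src) {
  c("COUNT", "FETCH", "SUBTREE_QUERY", "COUNTRY_METADATA")
}

bold_fetch_taxon <- function(src, taxon) {
  stmt <- build_bold_taxon_query(taxon)
  url <- paste0(src$base_url, "?", stmt$text)
  txt <- live_request(src, url)
  if (!nzchar(trimws(txt))) return(empty_records())
  df <- utils::read.delim(text = txt, sep = "\t", quote = "",
                          colClasses = "character",
                          check.names = FALSE)
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else
    rep(NA_character_, nrow(df))
  lineage <- vapply(seq_len(nrow(df)), function(i) {
    make_lineage(phylum = col("phylum_name")[i],
                 class = col("class_name")[i],
                 order = col("order_name")[i],
                 family = col("family_name")[i],
                 genus = col("genus_name")[i],
                 species = col("species_name")[i])
  }, character(1))
  seqs <- col("nucleotides")
  as_records(data.frame(
    source_db = "BOLD", accession = col("processid"),
    organism = col("species_name"), lineage = lineage,
    marker = col("markercode"),
    seq_length = ifelse(is.na(seqs) | seqs == "", NA_integer_,
                        nchar(gsub("-", "", seqs, fixed = TRUE))),
    country = col("country"), genbank_xref = col("genbank_accession"),
    sequence = seqs, stringsAsFactors = FALSE))
}

#' @export
count_matches.bold_source <- function(src, organism, group,
                                      filters = filter_spec()) {
  recs <- bold_fetch_taxon(src, organism)
  nrow(match_records(recs, organism, group, filters))
}

#' @export
fetch_records.bold_source <- function(src, organism, group,
                                      filters = filter_spec(),
                                      want_sequence = TRUE) {
  recs <- bold_fetch_taxon(src, organism)
  out <- match_records(recs, organism, group, filters)
  out <- out[order(out$accession), , drop = FALSE]
  if (!want_sequence) out$sequence <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
count_subtree.bold_source <- function(src, rank, taxon, group,
                                      filters = filter_spec()) {
  recs <- bold_fetch_taxon(src, taxon)
  if (nrow(recs) == 0) return(0L)
  keep <- !is.na(recs$marker) &
    norm_name(recs$marker) %in% tolower(group$synonyms)
  recs <- recs[keep, , drop = FALSE]
  recs <- apply_length_filter(recs, filters$min_length, filters$max_length)
  recs <- apply_country_filter(recs, filters$countries)
  nrow(recs)
}
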