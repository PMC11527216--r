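# Deterministic construction of database query statements. Equal inputs
# always produce byte-identical statement text, so exported statements
# can be replayed against the database web interfaces.

#' Build an Entrez (NCBI Nucleotide) search term
#'
#' In `"fielded"` mode (the default) the organism is searched in the
#' `[ORGN]` field and each synonym of the barcode group in the `[GENE]`
#' field; `"all_fields"` relaxes both to `[All Fields]` for records with
#' incomplete gene metadata. Synonyms are OR-ed inside one statement in
#' the group's declared order. Length bounds add an NCBI `[SLEN]` range
#' clause; a single bound fills the other side with 1 or 99999999 (NCBI
#' has no one-sided range).
#'
#' @param organism Scientific name to search (non-empty; embedded double
#'   quotes are rejected rather than escaped — NCBI term syntax has no
#'   portable escape).
#' @param group A [barcode_group()].
#' @param mode `"fielded"` or `"all_fields"`.
#' @param filters A [filter_spec()]; only the length bounds affect the
#'   term.
#' @return A [search_statement()] targeting NCBI.
#' @export
#' @examples
#' g <- barcode_group("CO1", c("COI", "COX1"))
#' build_entrez_term("Xenopus laevis", g)$text
build_entrez_term <- function(organism, group,
                              mode = c("fielded", "all_fields"),
                              filters = filter_spec()) {
  mode <- match.arg(mode)
  organism <- squish(organism)
  if (!nzchar(organism)) rc_abort("invalid_name", "organism name is empty")
  if (grepl('"', organism, fixed = TRUE)) {
    rc_abort("invalid_name",
             sprintf("organism name contains a double quote: %s", organism))
  }
  stopifnot(inherits(group, "barcode_group"))
  tags <- if (mode == "fielded") c("[ORGN]", "[GENE]") else
    c("[All Fields]", "[All Fields]")
  syn_clause <- paste0('"', group$synonyms, '"', tags[2], collapse = " OR ")
  text <- sprintf('("%s"%s) AND (%s)', organism, tags[1], syn_clause)
  lo <- filters$min_length
  hi <- filters$max_length
  if (!is.null(lo) || !is.null(hi)) {
    lo <- lo %||% 1L
    hi <- hi %||% 99999999L
    text <- paste0(text,
                   sprintf(' AND ("%d"[SLEN] : "%d"[SLEN])',
                           as.integer(lo), as.integer(hi)))
  }
  search_statement("NCBI", text, organism, group$canonical)
}

#' Build a BOLD taxon query
#'
#' Targets BOLD's combined specimen+sequence retrieval for a taxon.
#' BOLD resolves the taxon server-side with subtree semantics: querying
#' a genus returns records for all species beneath it.
#'
#' @param taxon A taxon name at any rank (non-empty).
#' @return A [search_statement()] targeting BOLD; `text` is the
#'   query-string fragment for the combined API.
#' @export
build_bold_taxon_query <- function(taxon) {
  taxon <- squish(taxon)
  if (!nzchar(taxon)) rc_abort("invalid_name", "taxon name is empty")
  if (grepl('"', taxon, fixed = TRUE)) {
    rc_abort("invalid_name",
             sprintf("taxon name contains a double quote: %s", taxon))
  }
  text <- paste0("taxon=", utils::URLencode(taxon, reserved = TRUE),
                 "&format=tsv")
  search_statement("BOLD", text, taxon, NA_character_)
}

#' Check bracket/quote balance of a statement
#'
#' @param text Statement text.
#' @return `TRUE` when double quotes pair up and `()`/`[]` nest
#'   correctly, else `FALSE`.
#' @export
check_statement_balance <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (sum(chars == '"') %% 2 != 0) return(FALSE)
  depth_p <- 0L
  depth_b <- 0L
  for (ch in chars) {
    if (ch == "(") depth_p <- depth_p + 1L
    else if (ch == ")") depth_p <- depth_p - 1L
    else if (ch == "[") depth_b <- depth_b + 1L
    else if (ch == "]") depth_b <- depth_b - 1L
    if (depth_p < 0 || depth_b < 0) return(FALSE)
  }
  depth_p == 0L && depth_b == 0L
}

#' Serialize search statements for export
#'
#' One statement per line, each preceded by a comment line
#' `# <db> <organism> <barcode>`, in input order. The output is
#' byte-reproducible so exported statement files diff cleanly across
#' runs.
#'
#' @param stmts A list of [search_statement()] objects.
#' @return A single string (LF line endings, trailing newline; empty
#'   string for an empty list).
#' @export
export_search_statements <- function(stmts) {
  if (length(stmts) == 0) return("")
  lines <- unlist(lapply(stmts, function(s) {
    bc <- if (is.na(s$barcode)) "-" else s$barcode
    c(sprintf("# %s %s %s", s$target_db, s$organism, bc), s$text)
  }))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write exported search statements to a file
#'
#' @param stmts A list of [search_statement()] objects.
#' @param path Output path (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_search_statements <- function(stmts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(export_search_statements(stmts), con, eos = NULL,
            useBytes = TRUE)
  invisible(path)
}
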