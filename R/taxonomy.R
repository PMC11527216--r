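# Name resolution (corrections are appended to the user's list, never
# substituted) and rank-fallback search up the taxonomic backbone:
# species first, then genus -> family -> order when the species-level
# count is zero. A species missing from the backbone is flagged
# unregistered and never searched at broader ranks.

#' Identity name resolver
#'
#' @return A resolver (function `name -> character vector of
#'   corrections`) that never proposes corrections.
#' @export
identity_resolver <- function() {
  function(name) character(0)
}

#' Table-driven name resolver
#'
#' The offline default: corrections come from a user-supplied table
#' (CSV with columns `wrong_name,correct_name`), matched
#' case-insensitively.
#'
#' @param table A data.frame with columns `wrong_name`, `correct_name`,
#'   or a path to such a CSV.
#' @return A resolver function; proposed corrections carry a
#'   `note` attribute naming the mapping source.
#' @export
table_resolver <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table, colClasses = "character")
  stopifnot(all(c("wrong_name", "correct_name") %in% names(table)))
  wrong <- norm_name(table$wrong_name)
  function(name) {
    hits <- table$correct_name[wrong == norm_name(name)]
    hits <- unique(squish(hits))
    if (length(hits) > 0) attr(hits, "note") <- "correction table"
    hits
  }
}

#' Resolve organism names, appending corrections
#'
#' Corrections are appended after the user's original name — the
#' original is never overridden — and every applied correction is
#' logged with its source. A failing resolver degrades to identity
#' resolution with a warning, never an error.
#'
#' @param names Character vector of input organism names.
#' @param resolver A resolver function (see [identity_resolver()],
#'   [table_resolver()]).
#' @return A list of [organism_query()] objects, one per input name.
#' @export
resolve_names <- function(names, resolver = identity_resolver()) {
  lapply(names, function(nm) {
    corr <- tryCatch(resolver(nm), error = function(e) {
      rc_warn("resolver_failure",
              sprintf("name resolver failed for \"%s\" (%s); using input as-is",
                      nm, conditionMessage(e)))
      character(0)
    })
    note <- attr(corr, "note") %||% "resolver"
    corr <- setdiff(squish(as.character(corr)), squish(nm))
    log <- if (length(corr) > 0) {
      data.frame(original = nm, correction = corr, note = note,
                 stringsAsFactors = FALSE)
    } else NULL
    organism_query(nm, corr, log)
  })
}

#' Look up a name's lineage in a taxonomy backbone
#'
#' @param name Scientific name (matched case-insensitively).
#' @param backbone A data.frame with columns `name`, `lineage` (the
#'   snapshot/CRUX backbone layout), or a `snapshot_source` whose
#'   backbone is used.
#' @return A named character vector over the rank vocabulary (see
#'   [parse_lineage()]), or `NULL` when the name is not registered in
#'   the backbone. Unregistered names trigger the documented all-zeros
#'   behavior in [fallback_search()].
#' @export
lineage_of <- function(name, backbone) {
  if (inherits(backbone, "snapshot_source")) backbone <- backbone$backbone
  if (is.null(backbone) || nrow(backbone) == 0) return(NULL)
  hit <- which(norm_name(backbone$name) == norm_name(name))
  if (length(hit) == 0) return(NULL)
  parse_lineage(backbone$lineage[hit[1]])
}

#' Rank-fallback search for one organism
#'
#' The species-level count is computed first, pooled over the query's
#' resolved names. If positive, only the species row is returned — no
#' broader search is issued. If zero and the organism is registered in
#' the backbone, its genus, family and order ancestors are additionally
#' counted (subtree semantics) in that fixed order, all reported. If
#' the organism is not registered, the species row (count 0) is
#' returned with the `unregistered` attribute set and no ancestor
#' query is made — walking up the tree is impossible without a
#' backbone entry.
#'
#' When the backbone genus differs from the first word of the binomial
#' (a moved species, e.g. a *Lithobates* placed under *Aquarana*), the
#' backbone's genus is walked and the divergence is raised as a
#' `refcov_taxonomy_drift` warning.
#'
#' @param src A record source.
#' @param oq An [organism_query()] (a bare name is accepted).
#' @param group A [barcode_group()].
#' @param backbone Taxonomy backbone (see [lineage_of()]).
#' @param filters A [filter_spec()].
#' @param ranks Fallback rank ladder (default genus, family, order).
#' @return A data.frame with columns `rank`, `taxon`, `count`, plus
#'   attributes `unregistered` (logical) and `query_log` (data.frame of
#'   every source query issued: `rank`, `taxon`).
#' @export
fallback_search <- function(src, oq, group, backbone,
                            filters = filter_spec(),
                            ranks = c("genus", "family", "order")) {
  if (is.character(oq)) oq <- organism_query(oq)
  stopifnot(inherits(oq, "organism_query"))
  log <- data.frame(rank = character(0), taxon = character(0),
                    stringsAsFactors = FALSE)
  total <- 0L
  for (nm in oq$resolved_names) {
    log <- rbind(log, data.frame(rank = "species", taxon = nm,
                                 stringsAsFactors = FALSE))
    total <- total + count_matches(src, nm, group, filters)
  }
  res <- data.frame(rank = "species", taxon = oq$input_name,
                    count = as.integer(total), stringsAsFactors = FALSE)
  unregistered <- FALSE
  if (total == 0L) {
    lin <- NULL
    for (nm in oq$resolved_names) {
      lin <- lineage_of(nm, backbone)
      if (!is.null(lin)) break
    }
    if (is.null(lin)) {
      unregistered <- TRUE
    } else {
      first_word <- strsplit(oq$input_name, " ", fixed = TRUE)[[1]][1]
      if (!is.na(lin[["genus"]]) &&
          norm_name(lin[["genus"]]) != norm_name(first_word)) {
        rc_warn("taxonomy_drift", sprintf(
          "\"%s\": backbone places it under genus %s; walking the backbone's tree",
          oq$input_name, lin[["genus"]]))
      }
      for (rk in ranks) {
        taxon <- lin[[rk]]
        if (is.na(taxon)) next
        log <- rbind(log, data.frame(rank = rk, taxon = taxon,
                                     stringsAsFactors = FALSE))
        n <- count_subtree(src, rk, taxon, group, filters)
        res <- rbind(res, data.frame(rank = rk, taxon = taxon,
                                     count = as.integer(n),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  attr(res, "unregistered") <- unregistered
  attr(res, "query_log") <- log
  res
}
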