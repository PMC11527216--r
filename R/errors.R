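# Classed conditions so callers can branch on failure kind
# (e.g. SOURCE_UNAVAILABLE is never conflated with a true zero count).

rc_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ...,
    class = c(paste0("refcov_", class), "refcov_error")))
}

rc_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ...,
    class = c(paste0("refcov_", class), "refcov_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse internal whitespace runs and trim; NA passes through
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

norm_name <- function(x) tolower(squish(x))
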