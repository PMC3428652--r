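#' @importFrom data.table data.table := .N .SD setkey as.data.table rbindlist
#' @importFrom utils head tail
NULL

# Classed conditions so callers (and the CLI) can distinguish bad input syntax
# from referential problems.
cssn_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cssn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

parse_error     <- function(msg, ...) cssn_error("cssn_parse_error", msg, ...)
integrity_error <- function(msg, ...) cssn_error("cssn_integrity_error", msg, ...)
lookup_error    <- function(msg, ...) cssn_error("cssn_lookup_error", msg, ...)
domain_error    <- function(msg, ...) cssn_error("cssn_domain_error", msg, ...)

# Read line-oriented input from a character vector of lines, a single file
# path, or a connection. A length-1 string containing a newline is treated as
# raw text.
as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (!is.character(x)) parse_error("expected lines, text, or a file path")
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  x
}

# Split one pipe-delimited record with a trailing pipe. strsplit() drops
# trailing empty fields, so the field count is taken from the pipe count.
split_rrf <- function(line) {
  n <- lengths(gregexpr("|", line, fixed = TRUE))
  if (is.na(n) || n < 1L) n <- 0L
  fields <- strsplit(line, "|", fixed = TRUE)[[1L]]
  length(fields) <- n          # pad dropped trailing empties with NA
  fields[is.na(fields)] <- ""
  fields
}

#' Canonical key for a signature
#'
#' A signature is an order-free, non-empty set of semantic-type identifiers
#' (TUIs). Its canonical key is the sorted TUIs joined by `"+"`, so that
#' `{A, B}` and `{B, A}` map to the same key.
#'
#' @param tuis Character vector of TUIs (duplicates allowed; they are merged).
#' @return A single string, e.g. `"T116+T129"`.
#' @seealso [sig_members()] for the inverse.
#' @export
sig_key <- function(tuis) {
  if (length(tuis) == 0L) domain_error("a signature must be non-empty")
  paste(sort(unique(tuis)), collapse = "+")
}

#' Member TUIs of a signature key
#'
#' @param key A signature key as produced by [sig_key()].
#' @return Character vector of TUIs, sorted.
#' @export
sig_members <- function(key) strsplit(key, "+", fixed = TRUE)[[1L]]

sig_size <- function(key) lengths(strsplit(key, "+", fixed = TRUE))

# is a a proper subset of b? (keys)
is_proper_subset <- function(a, b) {
  ma <- sig_members(a); mb <- sig_members(b)
  length(ma) < length(mb) && all(ma %in% mb)
}

# Maximal elements (subset order) of the available signatures that are proper
# subsets of `key`. This is the parent rule shared by IS-A derivation and by
# relaxation candidate search.
maximal_proper_subsets <- function(key, available) {
  cand <- available[vapply(available, is_proper_subset, logical(1L), b = key)]
  if (length(cand) == 0L) return(character(0L))
  keep <- vapply(cand, function(s) {
    !any(vapply(cand, function(t) is_proper_subset(s, t), logical(1L)))
  }, logical(1L))
  sort(unname(cand[keep]))
}

# Run code with a private RNG stream so generators are deterministic without
# disturbing the caller's random state.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
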