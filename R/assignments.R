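#' Read concept-to-semantic-type assignments (MRSTY dialect)
#'
#' Reads the Metathesaurus MRSTY.RRF format (`CUI|TUI|STN|STY|ATUI|CVF` with a
#' trailing pipe, no header) or a minimal two-column TSV (`cui<TAB>tui`, with
#' an optional `cui\ttui` header). The dialect is auto-detected from the first
#' data line.
#'
#' @param x Lines, raw text, a file path or a connection.
#' @return A data frame of `(cui, tui)` pairs in file order; duplicate pairs
#'   are preserved at this stage.
#' @details A pipe-dialect line with fewer than 2 fields, or a TSV line with
#'   fewer than 2 columns, raises a parse error naming the line.
#' @examples
#' read_mrsty(c("C0004609|T116|||||", "C0004609|T121|||||"))
#' @export
read_mrsty <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(cui = character(), tui = character(), stringsAsFactors = FALSE))
  }
  tsv <- grepl("\t", lines[[1L]], fixed = TRUE)
  sep <- if (tsv) "\t" else "|"
  nsep <- vapply(gregexpr(sep, lines, fixed = TRUE),
                 function(m) if (m[[1L]] == -1L) 0L else length(m), integer(1L))
  # k separators delimit k+1 fields in TSV; in the pipe dialect the trailing
  # pipe closes the last field, so k pipes mean k fields
  nfields <- if (tsv) nsep + 1L else nsep
  bad <- which(nfields < 2L)
  if (length(bad)) {
    parse_error("assignment line %d: expected at least 2 fields, got %d",
                bad[[1L]], nfields[[bad[[1L]]]])
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  short <- which(lengths(fields) < 2L)   # e.g. an empty trailing field
  if (length(short)) {
    parse_error("assignment line %d: expected at least 2 fields, got %d",
                short[[1L]], lengths(fields)[[short[[1L]]]])
  }
  cui <- vapply(fields, `[[`, character(1L), 1L)
  tui <- vapply(fields, `[[`, character(1L), 2L)
  if (tsv && tolower(cui[[1L]]) == "cui" && tolower(tui[[1L]]) == "tui") {
    cui <- cui[-1L]; tui <- tui[-1L]
  }
  out <- data.frame(cui = cui, tui = tui, stringsAsFactors = FALSE)
  if (any(!nzchar(out$cui))) {
    parse_error("assignment line %d: empty concept identifier",
                which(!nzchar(out$cui))[1L])
  }
  rownames(out) <- NULL
  out
}

#' Restrict an assignment table to the chemical subtree
#'
#' Implements the scoping rule of the derivation: a concept carrying at least
#' one chemical semantic type keeps exactly its chemical types and drops the
#' non-chemical ones (e.g. *Soap*, assigned both Lipid and the non-chemical
#' Manufactured Object, is kept as a chemical with Lipid only); a concept with
#' no chemical type is excluded entirely. Duplicate `(cui, tui)` pairs are
#' merged silently.
#'
#' @param pairs A data frame of `(cui, tui)` pairs from [read_mrsty()], or an
#'   already-restricted `assignment_table` (returned unchanged, so the
#'   operation is idempotent).
#' @param chemical_set Character vector of TUIs forming the chemical subtree,
#'   typically `subtree(net, "Chemical")`.
#' @return An `assignment_table`: list with `pairs` (restricted `(cui, tui)`
#'   data frame), `mixed_count` (number of concepts that carried both chemical
#'   and non-chemical types), `n_concepts`, and `chemical_set`.
#' @export
restrict_to_chemical <- function(pairs, chemical_set) {
  if (inherits(pairs, "assignment_table")) return(pairs)
  if (length(chemical_set) == 0L) domain_error("chemical_set must be non-empty")
  dt <- unique(data.table::as.data.table(pairs[, c("cui", "tui")]))
  dt[, chem := tui %in% chemical_set]
  status <- dt[, .(has_chem = any(chem), has_non = any(!chem)), by = cui]
  mixed <- sum(status$has_chem & status$has_non)
  keep <- dt[chem == TRUE, c("cui", "tui")]
  data.table::setkey(keep, cui, tui)
  out <- as.data.frame(keep)
  rownames(out) <- NULL
  structure(list(pairs = out,
                 mixed_count = as.integer(mixed),
                 n_concepts = length(unique(out$cui)),
                 chemical_set = chemical_set),
            class = "assignment_table")
}

#' @export
print.assignment_table <- function(x, ...) {
  cat(sprintf("assignment_table: %d concepts, %d (concept, type) pairs, %d mixed chemical/non-chemical concepts\n",
              x$n_concepts, nrow(x$pairs), x$mixed_count))
  invisible(x)
}

#' Index concepts by exact signature
#'
#' Groups the concepts of a restricted assignment table by their exact
#' combination of chemical semantic types (their signature). The extents of
#' the signatures are pairwise disjoint and together cover every concept in
#' the table, i.e. they partition it: this partition is what gets reified
#' into refined types.
#'
#' @param table An `assignment_table` from [restrict_to_chemical()].
#' @return A `signature_index`: list with `signatures` (named list: signature
#'   key to member TUIs), `extents` (named list: key to CUIs), and `counts`
#'   (named integer extent sizes).
#' @export
build_index <- function(table) {
  stopifnot(inherits(table, "assignment_table"))
  if (nrow(table$pairs) == 0L) {
    return(structure(list(signatures = list(), extents = list(),
                          counts = integer(0L)),
                     class = "signature_index"))
  }
  dt <- data.table::as.data.table(table$pairs)
  per <- dt[, .(key = paste(sort(tui), collapse = "+")), by = cui]
  extents <- split(per$cui, per$key)
  extents <- lapply(extents, sort)
  keys <- names(extents)
  structure(list(
    signatures = stats::setNames(lapply(keys, sig_members), keys),
    extents = extents,
    counts = vapply(extents, length, integer(1L))
  ), class = "signature_index")
}

#' @export
print.signature_index <- function(x, ...) {
  cat(sprintf("signature_index: %d signatures over %d concepts (%d singleton, %d intersection)\n",
              length(x$counts), sum(x$counts),
              sum(sig_size(names(x$counts)) == 1L),
              sum(sig_size(names(x$counts)) >= 2L)))
  invisible(x)
}
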