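#' Parse semantic-type definitions (SRDEF dialect)
#'
#' Reads the NLM SRDEF relational format: one pipe-delimited record per line
#' with a trailing pipe, where field 1 is the record type (`"STY"` for a
#' semantic type, `"RL"` for a relation label), field 2 the type unique
#' identifier (TUI), field 3 the display name and field 4 the dotted tree
#' number. Only `"STY"` records are returned; `"RL"` records are discarded.
#'
#' @param x Lines, raw text, a file path or a connection (see Details).
#' @return A data frame with columns `tui`, `name`, `tree_number`,
#'   `definition`, one row per semantic type.
#' @details Input may be given as a character vector of lines, a single string
#'   containing newlines, a path to a file, or a connection. Records with fewer
#'   than 10 pipe-separated fields raise a parse error naming the line; a
#'   duplicated TUI or display name raises an integrity error.
#' @examples
#' parse_srdef("STY|T109|Organic Chemical|A1.4.1.2.1|def|||||orch|")
#' @export
parse_srdef <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- split_rrf(lines[[i]])
    if (length(f) < 10L) {
      parse_error("SRDEF line %d: expected >= 10 pipe-separated fields, got %d",
                  i, length(f))
    }
    if (f[[1L]] != "STY") next
    recs[[i]] <- data.frame(tui = f[[2L]], name = f[[3L]],
                            tree_number = f[[4L]], definition = f[[5L]],
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(tui = character(), name = character(),
               tree_number = character(), definition = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(out$tui)) {
    integrity_error("duplicate TUI in SRDEF input: %s",
                    paste(unique(out$tui[duplicated(out$tui)]), collapse = ", "))
  }
  if (anyDuplicated(out$name)) {
    integrity_error("duplicate type name in SRDEF input: %s",
                    paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Parse semantic-network structure records (SRSTR dialect)
#'
#' Reads `STY1|RL|STY2|LS|` records and keeps only defined IS-A links
#' (relation `"isa"`, link status `"D"`). Type names (or TUIs) are resolved
#' against a set of parsed semantic types.
#'
#' @param x Lines, raw text, a file path or a connection.
#' @param types Data frame of semantic types from [parse_srdef()].
#' @return A data frame of IS-A edges with columns `child`, `parent` (TUIs).
#' @details Records whose relation is not `"isa"` or whose link status is not
#'   `"D"` are skipped, as are records with an empty endpoint (the format uses
#'   these for hierarchy roots). An endpoint that resolves to neither a known
#'   name nor a known TUI raises an integrity error listing it.
#' @examples
#' sty <- parse_srdef(c(
#'   "STY|T121|Pharmacologic Substance|A1.4.1.1.1|d|||||phsu|",
#'   "STY|T195|Antibiotic|A1.4.1.1.1.1|d|||||antb|"))
#' parse_srstr("Antibiotic|isa|Pharmacologic Substance|D|", sty)
#' @export
parse_srstr <- function(x, types) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  resolve <- function(id) {
    hit <- match(id, types$name)
    if (is.na(hit)) hit <- match(id, types$tui)
    if (is.na(hit)) integrity_error("SRSTR refers to unknown semantic type '%s'", id)
    types$tui[[hit]]
  }
  out <- list()
  for (i in seq_along(lines)) {
    f <- split_rrf(lines[[i]])
    if (length(f) < 4L) {
      parse_error("SRSTR line %d: expected 4 pipe-separated fields, got %d",
                  i, length(f))
    }
    if (f[[2L]] != "isa" || f[[4L]] != "D") next
    if (!nzchar(f[[1L]]) || !nzchar(f[[3L]])) next
    out[[length(out) + 1L]] <-
      data.frame(child = resolve(f[[1L]]), parent = resolve(f[[3L]]),
                 stringsAsFactors = FALSE)
  }
  edges <- if (length(out)) do.call(rbind, out) else
    data.frame(child = character(), parent = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  unique(edges)
}

#' Assemble a semantic network
#'
#' Combines parsed type definitions and IS-A edges into a validated network
#' object. The IS-A relation must be acyclic, every edge endpoint must be a
#' known type, no type may carry two parents, and wherever both ends of an
#' edge have tree numbers the parent's number must be a proper dotted prefix
#' of the child's.
#'
#' @param types Data frame from [parse_srdef()].
#' @param edges Data frame from [parse_srstr()].
#' @return An object of class `semantic_network`.
#' @export
semantic_network <- function(types, edges) {
  stopifnot(is.data.frame(types), is.data.frame(edges))
  bad <- setdiff(unique(c(edges$child, edges$parent)), types$tui)
  if (length(bad)) {
    integrity_error("IS-A edges mention unknown TUIs: %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(edges$child)) {
    integrity_error("type(s) with more than one parent: %s",
                    paste(unique(edges$child[duplicated(edges$child)]), collapse = ", "))
  }
  parent <- stats::setNames(edges$parent, edges$child)
  # cycle check: follow parent chains; a chain longer than the node count loops
  for (start in names(parent)) {
    cur <- start
    for (step in seq_len(length(types$tui) + 1L)) {
      cur <- unname(parent[cur])
      if (is.na(cur)) break
      if (cur == start) integrity_error("IS-A cycle through %s", start)
    }
  }
  tn <- stats::setNames(types$tree_number, types$tui)
  for (i in seq_len(nrow(edges))) {
    ctn <- tn[[edges$child[i]]]; ptn <- tn[[edges$parent[i]]]
    if (nzchar(ctn %||% "") && nzchar(ptn %||% "") &&
        !startsWith(ctn, paste0(ptn, "."))) {
      integrity_error("tree number of %s (%s) is not nested under its parent %s (%s)",
                      edges$child[i], ctn, edges$parent[i], ptn)
    }
  }
  structure(list(types = types, edges = edges, parent = parent),
            class = "semantic_network")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.semantic_network <- function(x, ...) {
  cat(sprintf("semantic_network: %d types, %d IS-A edges\n",
              nrow(x$types), nrow(x$edges)))
  roots <- setdiff(x$types$tui, names(x$parent))
  cat("roots:", paste(x$types$name[match(roots, x$types$tui)], collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a semantic type to its TUI
#'
#' Types may be identified by TUI or by display name anywhere in the package;
#' the TUI is the canonical key.
#'
#' @param net A `semantic_network`.
#' @param st TUI or display name (vectorised).
#' @return Character vector of TUIs.
#' @export
st_tui <- function(net, st) {
  hit <- match(st, net$types$tui)
  miss <- is.na(hit)
  hit[miss] <- match(st[miss], net$types$name)
  if (anyNA(hit)) {
    lookup_error("unknown semantic type(s): %s", paste(st[is.na(hit)], collapse = ", "))
  }
  net$types$tui[hit]
}

#' Display name of a semantic type
#' @param net A `semantic_network`.
#' @param st TUI or display name (vectorised).
#' @return Character vector of display names.
#' @export
st_name <- function(net, st) {
  net$types$name[match(st_tui(net, st), net$types$tui)]
}

#' Subtree of a semantic type
#'
#' All IS-A descendants of `root`, including `root` itself. With
#' `root = "Chemical"` on the bundled fixture this is the 25-type chemical
#' subtree over which a specialty network is derived.
#'
#' @param net A `semantic_network`.
#' @param root TUI or display name of the subtree root.
#' @return Character vector of TUIs (root first, then breadth-first).
#' @export
subtree <- function(net, root) {
  r <- st_tui(net, root)
  kids <- split(net$edges$child, net$edges$parent)
  out <- r
  frontier <- r
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    nxt <- nxt[!is.na(nxt)]
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Ancestor chain of a semantic type
#'
#' The unique IS-A parent chain from `st`'s parent upward; empty for a root.
#'
#' @param net A `semantic_network`.
#' @param st TUI or display name.
#' @return Character vector of TUIs, nearest parent first.
#' @export
st_ancestors <- function(net, st) {
  cur <- st_tui(net, st)
  out <- character(0L)
  repeat {
    p <- unname(net$parent[cur])
    if (is.na(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}

#' Depth of a semantic type below a subtree root
#'
#' Number of IS-A steps from `st` up to `root`; 0 for the root itself. Drives
#' the deepest-first ordering of relaxation.
#'
#' @param net A `semantic_network`.
#' @param st TUI or display name (vectorised).
#' @param root Subtree root, default `"Chemical"`.
#' @return Integer vector of depths.
#' @export
st_depth <- function(net, st, root = "Chemical") {
  r <- st_tui(net, root)
  vapply(st_tui(net, st), function(t) {
    if (t == r) return(0L)
    chain <- st_ancestors(net, t)
    pos <- match(r, chain)
    if (is.na(pos)) domain_error("%s is not within the subtree of %s", t, root)
    pos
  }, integer(1L), USE.NAMES = FALSE)
}

#' Structural/functional axis of a chemical semantic type
#'
#' Chemicals are viewed from two perspectives: types under "Chemical Viewed
#' Structurally" are `structural`, types under "Chemical Viewed Functionally"
#' are `functional` (each axis root included), and "Chemical" itself is
#' `root`.
#'
#' @param net A `semantic_network` containing the chemical subtree.
#' @param st TUI or display name (vectorised).
#' @param root Chemical subtree root, default `"Chemical"`.
#' @return Character vector with values `"structural"`, `"functional"`,
#'   `"root"`.
#' @export
axis_of <- function(net, st, root = "Chemical") {
  r <- st_tui(net, root)
  struct_root <- st_tui(net, "Chemical Viewed Structurally")
  fun_root <- st_tui(net, "Chemical Viewed Functionally")
  vapply(st_tui(net, st), function(t) {
    if (t == r) return("root")
    chain <- c(t, st_ancestors(net, t))
    if (!(r %in% chain)) domain_error("%s is outside the subtree of %s", t, root)
    if (struct_root %in% chain) "structural"
    else if (fun_root %in% chain) "functional"
    else domain_error("%s is on neither the structural nor the functional axis", t)
  }, character(1L), USE.NAMES = FALSE)
}

# sort key that orders dotted tree numbers hierarchically even with
# multi-digit components
tree_sort_key <- function(tree_number) {
  vapply(strsplit(tree_number, ".", fixed = TRUE), function(p) {
    num <- suppressWarnings(sprintf("%03d", as.integer(p)))
    num[is.na(num)] <- sprintf("%3s", p[is.na(suppressWarnings(as.integer(p)))])
    paste(num, collapse = ".")
  }, character(1L))
}
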