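#' Reassignment candidates for an omitted signature
#'
#' When a concept's exact-signature intersection type falls below the
#' threshold, the closest available types are the maximal proper
#' sub-signatures among the network's types. Because every singleton
#' (pure-type) signature always exists, the candidate set is never empty.
#'
#' @param sig Signature (character vector of TUIs/names or a signature key).
#' @param available Character vector of available signature keys. Singleton
#'   keys for the signature's own members are always added.
#' @param net A `semantic_network`.
#' @return Character vector of candidate signature keys.
#' @export
relax_candidates <- function(sig, available, net) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  if (length(tuis) < 2L) domain_error("only intersection signatures have reassignment candidates")
  maximal_proper_subsets(sig_key(tuis), unique(c(available, tuis)))
}

#' Reassign to the largest-extent candidate
#'
#' First reassignment strategy: the concept joins the candidate type with the
#' largest extent. Ties are broken deterministically by larger signature size,
#' then by the lexicographically smaller tuple of sorted type names.
#'
#' @inheritParams relax_candidates
#' @param extent_size Named integer vector: exact extent size per signature
#'   key. Keys absent from it count as 0.
#' @return The chosen signature key.
#' @examples
#' net <- chem_fixture()
#' sizes <- c("T109+T125" = 62L, "T109+T129" = 136L)
#' reassign_largest(c("Organic Chemical", "Hormone", "Immunologic Factor"),
#'                  names(sizes), net, sizes)
#' @export
reassign_largest <- function(sig, available, net, extent_size) {
  cand <- relax_candidates(sig, available, net)
  sizes <- rep(0L, length(cand))
  if (length(extent_size)) {
    hit <- extent_size[cand]
    hit[is.na(hit)] <- 0L
    sizes <- as.integer(hit)
  }
  name_tuple <- vapply(cand, function(k) {
    paste(sort(st_name(net, sig_members(k))), collapse = "")
  }, character(1L))
  cand[order(-sizes, -sig_size(cand), name_tuple)][[1L]]
}

# members of sig eligible to relax in the current phase: all functional
# members while any remain, then all structural members (the two published
# worked traces relax only functional types; the phase order is a documented
# package choice)
relaxable_members <- function(tuis, net) {
  ax <- axis_of(net, tuis)
  if (any(ax == "functional")) tuis[ax == "functional"]
  else tuis[ax == "structural"]
}

#' One relaxation step
#'
#' Replaces the deepest eligible semantic type of the signature by its
#' semantic-network parent, merging duplicates. Functional types relax first
#' (deepest first; ties by lexicographic type name), then structural types;
#' the subtree root cannot relax.
#'
#' @param sig Signature (TUIs/names or key).
#' @param net A `semantic_network`.
#' @return List with `sig` (the new signature key), and `step`, a one-row data
#'   frame `(relaxed, replacement, result)` recording which type was relaxed
#'   into which parent.
#' @export
relax_step <- function(sig, net) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  if (length(tuis) == 1L && axis_of(net, tuis) == "root") {
    domain_error("the subtree root cannot be relaxed further")
  }
  elig <- relaxable_members(tuis, net)
  if (length(elig) == 0L) domain_error("no relaxable semantic type in signature")
  depth <- st_depth(net, elig)
  pick <- elig[order(-depth, st_name(net, elig))][[1L]]
  parent <- net$parent[[pick]]
  out <- unique(c(setdiff(tuis, pick), parent))
  list(sig = sig_key(out),
       step = data.frame(relaxed = pick, replacement = parent,
                         result = sig_key(out), stringsAsFactors = FALSE))
}

#' Reassign by stepwise relaxation
#'
#' Second reassignment strategy: the signature's types are gradually
#' generalised toward ancestors, one step at a time, re-testing availability
#' after each step, until the current signature exists as a network type
#' (an intersection with extent at least `N`, or any singleton, the threshold
#' being inapplicable to pure types). The singleton of the subtree root is the
#' absorbing fallback, so the procedure is total.
#'
#' @param sig Signature (TUIs/names or key).
#' @param available Character vector of available signature keys (intersection
#'   types that survived the threshold). Singletons are always available.
#' @param net A `semantic_network`.
#' @param extent_size Optional named integer vector of exact extent sizes; when
#'   given together with `N`, an intersection key in `available` only counts as
#'   available if its extent is at least `N`.
#' @param N Optional minimum intersection extent, see `extent_size`.
#' @return A `relaxation_trace`: list with `start`, `steps` (data frame of
#'   `(relaxed, replacement, result)` rows) and `result` (the final key).
#' @examples
#' net <- chem_fixture()
#' tr <- reassign_relax(c("Organic Chemical", "Hormone", "Immunologic Factor"),
#'                      c("T109+T123"), net)
#' tr$result
#' @export
reassign_relax <- function(sig, available, net, extent_size = NULL, N = NULL) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  start <- sig_key(st_tui(net, sig))
  ok <- function(key) {
    if (sig_size(key) == 1L) return(TRUE)
    if (!(key %in% available)) return(FALSE)
    if (is.null(extent_size) || is.null(N)) return(TRUE)
    size <- extent_size[key]
    !is.na(size) && size >= N
  }
  cur <- start
  steps <- list()
  while (!ok(cur)) {
    st <- relax_step(cur, net)
    steps[[length(steps) + 1L]] <- st$step
    cur <- st$sig
  }
  structure(list(start = start,
                 steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(relaxed = character(), replacement = character(),
                              result = character(), stringsAsFactors = FALSE),
                 result = cur),
            class = "relaxation_trace")
}

#' @export
print.relaxation_trace <- function(x, ...) {
  cat("relaxation:", x$start, "->", x$result,
      sprintf("(%d step%s)\n", nrow(x$steps), if (nrow(x$steps) == 1L) "" else "s"))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps))) {
      cat(sprintf("  %d. %s -> %s  => %s\n", i, x$steps$relaxed[i],
                  x$steps$replacement[i], x$steps$result[i]))
    }
  }
  invisible(x)
}

#' Serialise a relaxation trace to JSON
#' @param x A `relaxation_trace`.
#' @param net Optional `semantic_network` used to add display names.
#' @return A JSON string.
#' @export
trace_to_json <- function(x, net = NULL) {
  doc <- list(start = x$start, result = x$result, steps = x$steps)
  if (!is.null(net)) {
    doc$start_types <- st_name(net, sig_members(x$start))
    doc$result_types <- st_name(net, sig_members(x$result))
  }
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
}
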