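#' Configuration for deriving a specialty network
#'
#' @param threshold Positive integer `N`: the minimum extent size an
#'   intersection type needs to enter the network. The threshold applies to
#'   intersection types only, never to pure (singleton) types.
#' @param strategy How concepts of omitted intersection types are handled:
#'   `"none"` leaves them uncovered, `"largest"` (alias `"largest_extent"`)
#'   adds each to the maximal available sub-signature with the largest extent,
#'   `"relax"` generalises types stepwise toward ancestors until an available
#'   type is reached.
#' @param root Root of the subtree being specialised, default `"Chemical"`.
#' @return A `build_config` list.
#' @export
build_config <- function(threshold = 1L,
                         strategy = c("none", "largest", "relax", "largest_extent"),
                         root = "Chemical") {
  strategy <- match.arg(strategy)
  if (strategy == "largest_extent") strategy <- "largest"
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) {
    domain_error("threshold must be a positive integer")
  }
  structure(list(threshold = threshold, strategy = strategy, root = root),
            class = "build_config")
}

#' Derive the refined types surviving a threshold
#'
#' Instantiates one pure type (PST) per semantic type of the subtree --
#' always, regardless of extent, including zero, so parent derivation always
#' has singleton fallbacks -- and one intersection type (IST) per observed
#' multi-type signature whose exact extent reaches the threshold.
#'
#' @param index A `signature_index` from [build_index()].
#' @param net A `semantic_network`.
#' @param config A `build_config`.
#' @return Data frame with columns `key`, `kind` (`"PST"`/`"IST"`), `size`
#'   (exact extent) and `n_members`.
#' @export
derive_types <- function(index, net, config = build_config()) {
  tuis <- subtree(net, config$root)
  keys <- names(index$counts)
  outside <- keys[!vapply(keys, function(k) all(sig_members(k) %in% tuis), logical(1L))]
  if (length(outside)) {
    domain_error("index contains signatures outside the subtree of %s: %s",
                 config$root, paste(utils::head(outside, 3L), collapse = ", "))
  }
  singleton <- stats::setNames(index$counts[tuis], tuis)
  singleton[is.na(singleton)] <- 0L
  ist_keys <- keys[sig_size(keys) >= 2L]
  ist_keys <- ist_keys[index$counts[ist_keys] >= config$threshold]
  out <- data.frame(
    key = c(tuis, ist_keys),
    kind = c(rep("PST", length(tuis)), rep("IST", length(ist_keys))),
    size = as.integer(c(singleton, index$counts[ist_keys])),
    stringsAsFactors = FALSE)
  out$n_members <- sig_size(out$key)
  rownames(out) <- NULL
  out
}

#' Derive the IS-A parents of a refined type
#'
#' A pure type mirrors the semantic network exactly: its only parent is the
#' singleton of its semantic-network parent (none for the subtree root). An
#' intersection type's parents are the maximal elements, under the subset
#' order, of the available signatures that are proper subsets of its own --
#' so a 3-way intersection may sit under three 2-way intersections, two, one
#' plus a singleton, or (when no 2-way subset survived) its three singletons.
#'
#' @param sig Signature (TUIs/names or key) of the type.
#' @param available Character vector of available signature keys; the
#'   singletons of the subtree are always treated as available.
#' @param net A `semantic_network`.
#' @param root Subtree root, default `"Chemical"`.
#' @return Character vector of parent signature keys (possibly empty for the
#'   root singleton).
#' @export
derive_parents <- function(sig, available, net, root = "Chemical") {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  if (length(tuis) == 1L) {
    if (tuis == st_tui(net, root)) return(character(0L))
    p <- unname(net$parent[tuis])
    return(if (is.na(p)) character(0L) else p)
  }
  maximal_proper_subsets(sig_key(tuis), unique(c(available, subtree(net, root))))
}

#' Build a Chemical Specialty Semantic Network
#'
#' Assembles the refined types surviving the threshold, derives the IS-A DAG,
#' renders display names, and maps every concept to its type. Concepts whose
#' exact-signature intersection type was omitted are either left uncovered
#' (`strategy = "none"`) or reassigned by the configured strategy; reassigned
#' concepts are recorded in the target type's assignment but do not inflate
#' its printed exact-extent size.
#'
#' @param index A `signature_index` from [build_index()].
#' @param net A `semantic_network`.
#' @param config A `build_config`.
#' @param rules Naming rule table, default [name_rules()].
#' @return A `cssn` object: list with `types` (data frame: `key`, `kind`,
#'   `size`, `assigned`, `name`, `label`, `n_parents`), `edges` (data frame
#'   `child`/`parent` keys), `assignment` (data frame `cui`, `key`, `relaxed`),
#'   `uncovered` (CUIs, non-empty only for `strategy = "none"` with `N > 1`),
#'   `exact_counts` (all observed signatures), `net`, `config`, and `traces`
#'   (relaxation traces per omitted signature when `strategy = "relax"`).
#' @examples
#' net <- chem_fixture()
#' tab <- restrict_to_chemical(
#'   read_mrsty(generate_assignments(published_extent_spec(divisor = 10), net)),
#'   subtree(net, "Chemical"))
#' cssn <- build_cssn(build_index(tab), net, build_config(30, "relax"))
#' cssn
#' @export
build_cssn <- function(index, net, config = build_config(), rules = name_rules()) {
  types <- derive_types(index, net, config)
  available <- types$key
  ist_avail <- types$key[types$kind == "IST"]

  parents <- lapply(types$key, derive_parents, available = available,
                    net = net, root = config$root)
  edges <- data.frame(
    child = rep(types$key, lengths(parents)),
    parent = unlist(parents, use.names = FALSE) %||% character(0L),
    stringsAsFactors = FALSE)
  types$n_parents <- lengths(parents)
  types$name <- vapply(types$key, render_name, character(1L), net = net, rules = rules)
  types$label <- vapply(types$key, intersect_label, character(1L), net = net)

  observed <- names(index$counts)
  surviving <- intersect(observed, types$key)
  omitted <- setdiff(observed, types$key)

  assign_list <- lapply(surviving, function(k) {
    data.frame(cui = index$extents[[k]], key = k, relaxed = FALSE,
               stringsAsFactors = FALSE)
  })
  uncovered <- character(0L)
  traces <- list()
  if (length(omitted)) {
    if (config$strategy == "none") {
      uncovered <- sort(unlist(index$extents[omitted], use.names = FALSE))
    } else {
      for (k in omitted) {
        target <- if (config$strategy == "largest") {
          reassign_largest(k, available, net, extent_size = index$counts)
        } else {
          tr <- reassign_relax(k, ist_avail, net)
          traces[[k]] <- tr
          tr$result
        }
        assign_list[[length(assign_list) + 1L]] <-
          data.frame(cui = index$extents[[k]], key = target, relaxed = TRUE,
                     stringsAsFactors = FALSE)
      }
    }
  }
  assignment <- if (length(assign_list)) do.call(rbind, assign_list) else
    data.frame(cui = character(), key = character(), relaxed = logical(),
               stringsAsFactors = FALSE)
  rownames(assignment) <- NULL
  tot <- table(factor(assignment$key, levels = types$key))
  types$assigned <- as.integer(tot[types$key])

  structure(list(types = types, edges = edges, assignment = assignment,
                 uncovered = uncovered, exact_counts = index$counts,
                 traces = traces, net = net, config = config),
            class = "cssn")
}

#' @export
print.cssn <- function(x, ...) {
  cat(sprintf("Chemical Specialty Semantic Network (threshold N = %d, strategy = %s)\n",
              x$config$threshold, x$config$strategy))
  cat(sprintf("  %d types: %d pure + %d intersection; %d IS-A edges\n",
              nrow(x$types), sum(x$types$kind == "PST"), sum(x$types$kind == "IST"),
              nrow(x$edges)))
  cat(sprintf("  %d concepts assigned (%d by reassignment), %d uncovered; exact coverage %.1f%%\n",
              nrow(x$assignment), sum(x$assignment$relaxed), length(x$uncovered),
              100 * cssn_coverage(x)))
  invisible(x)
}

#' Exact-signature coverage of a specialty network
#'
#' The fraction of chemical concepts whose exact signature exists as a network
#' type, i.e. the concepts that needed no reassignment. Coverage is defined
#' before any relaxation, so it does not depend on the strategy; at `N = 1` it
#' is exactly 1.
#'
#' @param cssn A `cssn` from [build_cssn()].
#' @return A fraction in `[0, 1]` (`NaN` for an empty table).
#' @export
cssn_coverage <- function(cssn) {
  total <- sum(cssn$exact_counts)
  covered <- sum(cssn$exact_counts[names(cssn$exact_counts) %in% cssn$types$key])
  covered / total
}

#' Sweep the threshold value
#'
#' Rebuilds the network for each threshold and reports its size and coverage,
#' showing the tradeoff between network size and the share of concepts it
#' covers exactly.
#'
#' @param index A `signature_index`.
#' @param net A `semantic_network`.
#' @param thresholds Integer vector of threshold values.
#' @param root Subtree root, default `"Chemical"`.
#' @return Data frame with columns `N`, `type_count`, `coverage` (fraction),
#'   one row per threshold in the given order.
#' @export
threshold_sweep <- function(index, net, thresholds, root = "Chemical") {
  rows <- lapply(thresholds, function(n) {
    cfg <- build_config(n, "none", root)
    types <- derive_types(index, net, cfg)
    covered <- sum(index$counts[names(index$counts) %in% types$key])
    data.frame(N = as.integer(n), type_count = nrow(types),
               coverage = covered / sum(index$counts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a specialty network as JSON
#'
#' @param cssn A `cssn`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
cssn_to_json <- function(cssn, path = NULL) {
  nm <- stats::setNames(cssn$types$name, cssn$types$key)
  doc <- list(
    config = unclass(cssn$config),
    types = data.frame(
      key = cssn$types$key, kind = cssn$types$kind, name = cssn$types$name,
      label = cssn$types$label, extent_size = cssn$types$size,
      assigned_incl_relaxed = cssn$types$assigned, stringsAsFactors = FALSE),
    edges = data.frame(child = unname(nm[cssn$edges$child]),
                       parent = unname(nm[cssn$edges$parent]),
                       child_key = cssn$edges$child, parent_key = cssn$edges$parent,
                       stringsAsFactors = FALSE),
    uncovered = cssn$uncovered)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export the IS-A edges as a flat TSV list
#'
#' @param cssn A `cssn`.
#' @param path Optional file path for a two-column `child_name`/`parent_name`
#'   TSV; when `NULL` only the data frame is returned.
#' @return Data frame with columns `child_name`, `parent_name`.
#' @export
cssn_edges_tsv <- function(cssn, path = NULL) {
  nm <- stats::setNames(cssn$types$name, cssn$types$key)
  out <- data.frame(child_name = unname(nm[cssn$edges$child]),
                    parent_name = unname(nm[cssn$edges$parent]),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
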