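the <- new.env(parent = emptyenv())

#' The default type-naming rule table
#'
#' One rule per chemical semantic type: the form used when the type is the
#' rightmost (head) component of an intersection-type name, the shortened
#' modifier form used otherwise (unessential words such as "Substance" or
#' "Chemical" dropped), and the priority class that fixes left-to-right
#' ordering. The table ships as an editable TSV
#' (`inst/extdata/name_rules.tsv`) so curators can adjust forms without code
#' changes.
#'
#' @param path Optional path to an alternative rule TSV with columns `tui`,
#'   `name`, `head_form`, `modifier_form`, `priority_class`.
#' @return A data frame of naming rules.
#' @details Priority classes order name components as general-purpose
#'   functional < structural < specific functional, the rightmost (highest
#'   priority) component supplying the head: a Pharmacologic Steroid is first
#'   and foremost a steroid. The published example names place "Neuroreactive
#'   Substance or Biogenic Amine" with the general-purpose group, and
#'   "Indicator, Reagent, or Diagnostic Aid" with the specific group, although
#'   the printed record is contradictory for the latter; see the package
#'   vignette.
#' @export
name_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$name_rules)) {
      the$name_rules <- utils::read.delim(
        system.file("extdata", "name_rules.tsv", package = "cssn", mustWork = TRUE),
        stringsAsFactors = FALSE)
    }
    return(the$name_rules)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

class_rank <- c(root = 0L, general_functional = 1L, structural = 2L,
                specific_functional = 3L)

#' Priority class of a chemical semantic type
#'
#' @param net A `semantic_network`.
#' @param st TUI or display name (vectorised).
#' @param rules Naming rule table, default [name_rules()].
#' @return Character vector with values `"general_functional"`,
#'   `"structural"`, `"specific_functional"`, or `"root"` for the subtree
#'   root.
#' @export
priority_class <- function(net, st, rules = name_rules()) {
  tuis <- st_tui(net, st)
  hit <- match(tuis, rules$tui)
  if (anyNA(hit)) {
    domain_error("no naming rule for semantic type(s): %s (not a chemical type?)",
                 paste(tuis[is.na(hit)], collapse = ", "))
  }
  rules$priority_class[hit]
}

# components of a signature in display order (left to right):
# ascending priority class, ties by semantic-network tree number
ordered_components <- function(sig, net, rules = name_rules()) {
  tuis <- st_tui(net, sig)
  cls <- priority_class(net, tuis, rules)
  tn <- net$types$tree_number[match(tuis, net$types$tui)]
  tuis[order(class_rank[cls], tree_sort_key(tn))]
}

#' Render the display name of a signature
#'
#' A singleton signature keeps its semantic type's name unchanged. For an
#' intersection, components are ordered left to right by ascending priority
#' (general-purpose functional, then structural, then specific functional;
#' ties by tree-number order), the rightmost component contributes its head
#' form and the others their modifier forms.
#'
#' @param sig Signature: character vector of TUIs or names, or a signature key.
#' @param net A `semantic_network`.
#' @param rules Naming rule table, default [name_rules()].
#' @return A single display-name string.
#' @examples
#' net <- chem_fixture()
#' render_name(c("Amino Acid, Peptide, or Protein", "Immunologic Factor"), net)
#' @export
render_name <- function(sig, net, rules = name_rules()) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  if (length(tuis) == 0L) domain_error("a signature must be non-empty")
  if (length(tuis) == 1L) return(st_name(net, tuis))
  ord <- ordered_components(tuis, net, rules)
  hit <- match(ord, rules$tui)
  forms <- c(rules$modifier_form[hit[-length(hit)]],
             rules$head_form[hit[length(hit)]])
  paste(forms, collapse = " ")
}

#' Set-intersection style label of a signature
#'
#' The formal "A ∩ B" label, with structural components first and
#' components within an axis in tree-number order.
#'
#' @inheritParams render_name
#' @return A single string, e.g.
#'   `"Amino Acid, Peptide, or Protein ∩ Immunologic Factor"`.
#' @export
intersect_label <- function(sig, net) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  ax <- axis_of(net, tuis)
  ax_rank <- c(root = 0L, structural = 1L, functional = 2L)
  tn <- net$types$tree_number[match(tuis, net$types$tui)]
  ord <- tuis[order(ax_rank[ax], tree_sort_key(tn))]
  paste(st_name(net, ord), collapse = " ∩ ")
}

#' Placement parent for indented listings
#'
#' An intersection type has several parents in the IS-A graph; in an indented
#' listing it is displayed under the single parent with the highest naming
#' priority, i.e. the parent carrying the rightmost components of its rendered
#' name (for a pure type: its semantic-network parent).
#'
#' @param sig Signature (TUIs, names, or a key).
#' @param available Character vector of available signature keys (the CSSN's
#'   types); all singleton keys are assumed present.
#' @param net A `semantic_network`.
#' @param rules Naming rule table.
#' @return The parent signature key, or `NA_character_` for the subtree root.
#' @export
placement_parent <- function(sig, available, net, rules = name_rules()) {
  if (length(sig) == 1L && grepl("+", sig, fixed = TRUE)) sig <- sig_members(sig)
  tuis <- unique(st_tui(net, sig))
  if (length(tuis) == 1L) {
    return(unname(net$parent[tuis]))
  }
  key <- sig_key(tuis)
  parents <- maximal_proper_subsets(key, unique(c(available, tuis)))
  ord <- ordered_components(tuis, net, rules)
  score <- vapply(parents, function(p) {
    pm <- sig_members(p)
    s <- 0L
    for (k in seq_along(ord)) {
      if (ord[[length(ord) - k + 1L]] %in% pm) s <- k else break
    }
    # bonus when the parent's own ordering is exactly the child's suffix
    exact <- length(pm) <= length(ord) &&
      identical(ordered_components(pm, net, rules), tail(ord, length(pm)))
    s + if (exact && s == length(pm)) 0.5 else 0
  }, numeric(1L))
  parents[order(-score, -sig_size(parents), parents)][[1L]]
}
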