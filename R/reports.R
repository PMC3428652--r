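#' Indented listing of a specialty network
#'
#' Reproduces the published listing layout: pure types appear in
#' semantic-network order (depth-first by tree number, indented by depth);
#' the intersection types of each pure type's block follow in descending
#' order of exact extent, indented under their placement parent, each
#' preceded by one asterisk per parent beyond the placement parent.
#'
#' @param cssn A `cssn` from [build_cssn()].
#' @return Data frame with columns `label` (the formal intersection label),
#'   `size`, `name`, `kind`, `indent`, `asterisks`, `n_parents` and `text`
#'   (the ready-to-print indented row).
#' @export
cssn_listing <- function(cssn) {
  net <- cssn$net
  types <- cssn$types
  root <- st_tui(net, cssn$config$root)

  # placement parent per type (PSTs: semantic-network parent)
  place <- vapply(types$key, placement_parent, character(1L),
                  available = types$key, net = net)
  # resolve each IST to the pure-type block it is displayed in
  block_of <- function(key) {
    cur <- key
    while (sig_size(cur) > 1L) cur <- place[[cur]]
    cur
  }
  ist_keys <- types$key[types$kind == "IST"]
  blocks <- vapply(ist_keys, block_of, character(1L))

  pst_depth <- stats::setNames(st_depth(net, types$key[types$kind == "PST"],
                                        root = cssn$config$root),
                               types$key[types$kind == "PST"])
  chain_len <- function(key) {
    n <- 0L; cur <- key
    while (sig_size(cur) > 1L) { n <- n + 1L; cur <- place[[cur]] }
    n
  }

  # depth-first over pure types by tree number
  tn <- stats::setNames(net$types$tree_number, net$types$tui)
  kids <- split(net$edges$child, net$edges$parent)
  rows <- list()
  emit <- function(key, kind) {
    i <- match(key, types$key)
    indent <- if (kind == "PST") pst_depth[[key]] else
      pst_depth[[block_of(key)]] + chain_len(key)
    ast <- if (kind == "PST") 0L else types$n_parents[i] - 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      key = key, label = types$label[i], size = types$size[i],
      name = types$name[i], kind = kind, indent = indent, asterisks = ast,
      n_parents = types$n_parents[i],
      text = paste0(strrep("  ", indent), strrep("*", ast), types$name[i]),
      stringsAsFactors = FALSE)
  }
  visit <- function(tui) {
    emit(tui, "PST")
    mine <- ist_keys[blocks == tui]
    for (k in mine[order(-types$size[match(mine, types$key)],
                         types$name[match(mine, types$key)])]) emit(k, "IST")
    ch <- kids[[tui]]
    if (!is.null(ch)) {
      # structural axis first (the published ordering), then tree number
      ax <- c(root = 0L, structural = 1L, functional = 2L)[axis_of(net, ch)]
      for (c in ch[order(ax, tree_sort_key(tn[ch]))]) visit(c)
    }
  }
  visit(root)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare semantic-network and pure-type assignment counts
#'
#' For each chemical semantic type: the semantic-network style count, where a
#' concept is counted once per chemical type it carries, against the pure-type
#' count, where only concepts assigned exactly that single type are counted.
#'
#' @param table The `assignment_table` the network was built from.
#' @param cssn A `cssn`.
#' @return Data frame with columns `tui`, `name`, `sn_count`, `pst_count`,
#'   in depth-first semantic-network order.
#' @export
compare_sn <- function(table, cssn) {
  stopifnot(inherits(table, "assignment_table"))
  net <- cssn$net
  ordered <- cssn_listing(cssn)
  tuis <- ordered$key[ordered$kind == "PST"]
  sn <- table(factor(table$pairs$tui, levels = tuis))
  pst <- stats::setNames(cssn$types$size[match(tuis, cssn$types$key)], tuis)
  out <- data.frame(tui = tuis, name = st_name(net, tuis),
                    sn_count = as.integer(sn[tuis]),
                    pst_count = as.integer(pst[tuis]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Audit candidates: small intersection types
#'
#' Intersection types with very small extents often indicate inconsistent
#' semantic-type assignments; auditing uses a network built with threshold 1
#' and reviews intersection types of up to `max_extent` concepts, smallest
#' first.
#'
#' @param cssn A `cssn`, normally built with `threshold = 1` (a warning is
#'   issued otherwise, since larger thresholds have already dropped the
#'   candidates).
#' @param max_extent Largest extent size to report, default 6.
#' @return Data frame with columns `key`, `label`, `name`, `size` and a
#'   list-column `cuis` of extent members, ascending by size.
#' @export
audit_candidates <- function(cssn, max_extent = 6L) {
  if (cssn$config$threshold != 1L) {
    warning("audit expects a network built with threshold 1; ",
            "intersection types below N = ", cssn$config$threshold,
            " have already been dropped")
  }
  ist <- cssn$types[cssn$types$kind == "IST" &
                      cssn$types$size >= 1L & cssn$types$size <= max_extent, ]
  ist <- ist[order(ist$size, ist$key), ]
  members <- split(cssn$assignment$cui[!cssn$assignment$relaxed],
                   cssn$assignment$key[!cssn$assignment$relaxed])
  out <- data.frame(key = ist$key, label = ist$label, name = ist$name,
                    size = ist$size, stringsAsFactors = FALSE)
  out$cuis <- lapply(ist$key, function(k) sort(members[[k]]))
  rownames(out) <- NULL
  out
}
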