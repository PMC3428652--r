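#' Specify a synthetic assignment table
#'
#' A signature spec lists how many concepts carry each exact combination of
#' chemical semantic types, plus optional mixed rows whose concepts carry an
#' additional non-chemical type (exercising the restriction rule). Generation
#' is fully deterministic given the seed.
#'
#' @param rows List of `list(sig = <TUIs or names>, count = <n>)` entries, or
#'   a data frame with columns `sig` (signature keys or `";"`-separated
#'   names) and `count`.
#' @param mixed_rows Optional list of
#'   `list(sig = <chemical TUIs/names>, non_chemical = <TUI>, count = <n>)`.
#' @param seed Integer seed, default 1.
#' @return A `signature_spec` list.
#' @export
signature_spec <- function(rows, mixed_rows = list(), seed = 1L) {
  norm <- function(r) {
    if (is.null(r$count) || r$count < 0) domain_error("spec counts must be >= 0")
    s <- r$sig
    if (length(s) == 1L && grepl(";", s, fixed = TRUE)) {
      s <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    } else if (length(s) == 1L && grepl("+", s, fixed = TRUE)) {
      s <- sig_members(s)
    }
    list(sig = s, non_chemical = r$non_chemical, count = as.integer(r$count))
  }
  if (is.data.frame(rows)) {
    rows <- lapply(seq_len(nrow(rows)), function(i)
      list(sig = rows$sig[i], count = rows$count[i]))
  }
  structure(list(rows = lapply(rows, norm),
                 mixed_rows = lapply(mixed_rows, norm),
                 seed = as.integer(seed)),
            class = "signature_spec")
}

#' Generate an MRSTY-dialect assignment table from a spec
#'
#' Emits exactly `count` concepts per signature row, with fresh synthetic
#' concept identifiers (prefix `"S"`, so they cannot collide with real CUIs),
#' row order shuffled deterministically by the spec's seed. Mixed rows attach
#' their non-chemical TUI to every concept of the row.
#'
#' @param spec A `signature_spec`.
#' @param net A `semantic_network` used to resolve and validate the
#'   signatures' semantic types.
#' @return Character vector of MRSTY-dialect lines (`CUI|TUI|...|` records).
#' @seealso [write_mrsty()] to put the lines in a file, [read_mrsty()] to read
#'   them back.
#' @export
generate_assignments <- function(spec, net) {
  stopifnot(inherits(spec, "signature_spec"))
  all_rows <- c(spec$rows, spec$mixed_rows)
  if (length(all_rows) == 0L) return(character(0L))
  sigs <- lapply(all_rows, function(r) {
    s <- unique(st_tui(net, r$sig))   # unknown type -> lookup error
    c(s, r$non_chemical)
  })
  counts <- vapply(all_rows, `[[`, integer(1L), "count")
  n_concepts <- sum(counts)
  if (n_concepts == 0L) return(character(0L))
  cuis <- sprintf("S%07d", seq_len(n_concepts))
  row_of <- rep(seq_along(all_rows), counts)
  cui_list <- split(cuis, row_of)
  pairs <- data.table::rbindlist(lapply(seq_along(all_rows), function(i) {
    sg <- sigs[[i]]
    cs <- cui_list[[as.character(i)]]
    if (length(cs) == 0L) return(NULL)
    data.table::data.table(cui = rep(cs, each = length(sg)),
                           tui = rep(sg, times = length(cs)))
  }))
  names <- stats::setNames(net$types$name, net$types$tui)
  lines <- sprintf("%s|%s||%s|||", pairs$cui, pairs$tui,
                   ifelse(is.na(names[pairs$tui]), "", names[pairs$tui]))
  with_rng(spec$seed, sample(lines))
}

#' Write MRSTY-dialect lines to a file
#' @param lines Character vector from [generate_assignments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrsty <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' The published-extent fixture spec
#'
#' Encodes every extent size printed in the study as a synthetic-table spec:
#' the singleton (pure-type) extents of all 25 chemical semantic types, the
#' worked-example intersections around Organic Chemical, and the large
#' Amino Acid, Peptide, or Protein intersections. Together with the bundled
#' subtree fixture this reproduces the worked examples without the licensed
#' UMLS release.
#'
#' @param divisor Integer scale-down factor: every count is integer-divided by
#'   it (structure preserved), for fast reduced fixtures. Default 1 (the
#'   printed sizes).
#' @param seed Seed forwarded to the spec, default 2009.
#' @return A `signature_spec`.
#' @export
published_extent_spec <- function(divisor = 1L, seed = 2009L) {
  pst <- list(
    list(sig = "T103", count = 26L),     # Chemical
    list(sig = "T104", count = 248L),    # Chemical Viewed Structurally
    list(sig = "T109", count = 58347L),  # Organic Chemical
    list(sig = "T110", count = 4883L),   # Steroid
    list(sig = "T111", count = 537L),    # Eicosanoid
    list(sig = "T114", count = 4727L),   # Nucleic Acid, Nucleoside, or Nucleotide
    list(sig = "T115", count = 919L),    # Organophosphorus Compound
    list(sig = "T116", count = 16973L),  # Amino Acid, Peptide, or Protein
    list(sig = "T118", count = 6077L),   # Carbohydrate
    list(sig = "T119", count = 3494L),   # Lipid
    list(sig = "T120", count = 174L),    # Chemical Viewed Functionally
    list(sig = "T121", count = 14168L),  # Pharmacologic Substance
    list(sig = "T122", count = 3408L),   # Biomedical or Dental Material
    list(sig = "T123", count = 1026L),   # Biologically Active Substance
    list(sig = "T124", count = 20L),     # Neuroreactive Substance or Biogenic Amine
    list(sig = "T125", count = 147L),    # Hormone
    list(sig = "T126", count = 233L),    # Enzyme
    list(sig = "T127", count = 117L),    # Vitamin
    list(sig = "T129", count = 7181L),   # Immunologic Factor
    list(sig = "T130", count = 4350L),   # Indicator, Reagent, or Diagnostic Aid
    list(sig = "T131", count = 422L),    # Hazardous or Poisonous Substance
    list(sig = "T192", count = 125L),    # Receptor
    list(sig = "T195", count = 546L),    # Antibiotic
    list(sig = "T196", count = 1004L),   # Element, Ion, or Isotope
    list(sig = "T197", count = 2490L))   # Inorganic Chemical
  ist <- list(
    list(sig = c("T116", "T129"), count = 12662L),          # AAPP ∩ Immunologic Factor
    list(sig = c("T116", "T121"), count = 6537L),           # AAPP ∩ Pharmacologic Substance
    list(sig = c("T116", "T121", "T129"), count = 1940L),   # AAPP ∩ PS ∩ IF
    list(sig = c("T116", "T195"), count = 490L),            # AAPP ∩ Antibiotic
    list(sig = c("T121", "T129"), count = 1065L),           # PS ∩ Immunologic Factor
    list(sig = c("T109", "T121"), count = 76832L),          # OC ∩ Pharmacologic Substance
    list(sig = c("T109", "T125"), count = 62L),             # OC ∩ Hormone
    list(sig = c("T109", "T129"), count = 136L),            # OC ∩ Immunologic Factor
    list(sig = c("T109", "T123"), count = 4151L),           # OC ∩ Biologically Active Substance
    list(sig = c("T109", "T121", "T123"), count = 507L),    # OC ∩ PS ∩ BAS
    list(sig = c("T109", "T121", "T129"), count = 249L),    # OC ∩ PS ∩ IF
    list(sig = c("T109", "T125", "T129"), count = 1L))      # OC ∩ Hormone ∩ IF
  rows <- lapply(c(pst, ist), function(r) {
    r$count <- r$count %/% as.integer(divisor)
    r
  })
  signature_spec(rows, seed = seed)
}
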