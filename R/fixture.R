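#' The bundled 2009AA chemical-subtree fixture
#'
#' Loads the 25 chemical semantic types and their 24 IS-A edges (the subtree
#' rooted at "Chemical" of the UMLS 2009AA Semantic Network), assembled from
#' the public SRDEF/SRSTR relational files and shipped with the package so the
#' whole pipeline can run without the licensed UMLS release.
#'
#' @param source `"text"` reads the bundled SRDEF/SRSTR dialect files through
#'   the package parsers; `"json"` reads the versioned JSON document. Both
#'   yield the same network.
#' @return A `semantic_network` with 25 types and 24 edges.
#' @examples
#' net <- chem_fixture()
#' length(subtree(net, "Chemical"))
#' @export
chem_fixture <- function(source = c("text", "json")) {
  source <- match.arg(source)
  if (source == "text") {
    sty <- parse_srdef(system.file("extdata", "srdef_2009aa_chemical.txt",
                                   package = "cssn", mustWork = TRUE))
    edges <- parse_srstr(system.file("extdata", "srstr_2009aa_chemical.txt",
                                     package = "cssn", mustWork = TRUE), sty)
    semantic_network(sty, edges)
  } else {
    doc <- jsonlite::read_json(system.file("extdata", "chemical_subtree_2009aa.json",
                                           package = "cssn", mustWork = TRUE),
                               simplifyVector = TRUE)
    semantic_network(as.data.frame(doc$types, stringsAsFactors = FALSE),
                     as.data.frame(doc$edges, stringsAsFactors = FALSE))
  }
}
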