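# Shared fixtures and independent brute-force oracles.

fx <- chem_fixture()
CHEM <- subtree(fx, "Chemical")

tui_of <- function(...) st_tui(fx, c(...))
key_of <- function(...) sig_key(st_tui(fx, c(...)))

# Independent ancestor walk straight over the edge data frame.
walk_ancestors <- function(net, tui) {
  out <- character(0L)
  repeat {
    row <- match(tui, net$edges$child)
    if (is.na(row)) break
    tui <- net$edges$parent[[row]]
    out <- c(out, tui)
  }
  out
}

# Brute-force parent oracle: enumerate every non-empty proper subset of the
# signature, keep those available (singletons always are), then drop any kept
# subset strictly contained in another kept one.
oracle_parents <- function(members, available_keys) {
  members <- sort(members)
  subsets <- list()
  for (k in seq_len(length(members) - 1L)) {
    cmb <- utils::combn(members, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  keys <- vapply(subsets, paste, character(1L), collapse = "+")
  ok <- lengths(subsets) == 1L | keys %in% available_keys
  kept <- subsets[ok]
  maximal <- vapply(seq_along(kept), function(i) {
    !any(vapply(seq_along(kept), function(j) {
      i != j && length(kept[[i]]) < length(kept[[j]]) &&
        length(setdiff(kept[[i]], kept[[j]])) == 0L
    }, logical(1L)))
  }, logical(1L))
  sort(vapply(kept[maximal], paste, character(1L), collapse = "+"))
}

# Random assignment pairs over the chemical subtree, optionally with
# non-chemical types mixed in; returns a (cui, tui) data frame.
rand_pairs <- function(n_concepts, seed, p_multi = 0.5, p_nonchem = 0.1,
                       pool = CHEM) {
  withr::with_seed(seed, {
    cuis <- sprintf("R%06d", seq_len(n_concepts))
    k <- 1L + stats::rbinom(n_concepts, 2L, p_multi)
    pairs <- data.frame(cui = rep(cuis, k),
                        tui = sample(pool, sum(k), replace = TRUE),
                        stringsAsFactors = FALSE)
    extra <- cuis[stats::runif(n_concepts) < p_nonchem]
    if (length(extra)) {
      pairs <- rbind(pairs, data.frame(cui = extra, tui = "T073",
                                       stringsAsFactors = FALSE))
    }
    unique(pairs)
  })
}

rand_index <- function(n_concepts, seed, ...) {
  build_index(restrict_to_chemical(rand_pairs(n_concepts, seed, ...), CHEM))
}

# Dictionary-of-sorted-type-sets oracle for signature grouping.
oracle_index <- function(pairs, chemical_set) {
  per <- split(pairs$tui, pairs$cui)
  per <- lapply(per, function(t) sort(unique(intersect(t, chemical_set))))
  per <- per[lengths(per) > 0L]
  keys <- vapply(per, paste, character(1L), collapse = "+")
  split(names(per), keys)
}

# Fast published-extent index at a reduced scale, shared across tests.
published_index_d10 <- local({
  lines <- generate_assignments(published_extent_spec(divisor = 10), fx)
  build_index(restrict_to_chemical(read_mrsty(lines), CHEM))
})
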