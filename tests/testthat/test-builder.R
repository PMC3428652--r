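test_that("thresholding keeps large intersections, drops small ones, spares pure types", {
  idx <- published_index_d10
  cfg <- build_config(30, "none")   # divisor-10 scale of N = 300
  types <- derive_types(idx, fx, cfg)
  expect_true(key_of("Amino Acid, Peptide, or Protein", "Antibiotic")
              %in% types$key)      # 49 >= 30
  expect_false(key_of("Organic Chemical", "Pharmacologic Substance",
                      "Immunologic Factor") %in% types$key)  # 24 < 30
  # every pure type is present, even with a small or empty exact extent
  expect_equal(sum(types$kind == "PST"), 25L)
  expect_setequal(types$key[types$kind == "PST"], CHEM)

  # threshold floor: every observed signature becomes a type
  t1 <- derive_types(idx, fx, build_config(1, "none"))
  expect_setequal(t1$key, union(CHEM, names(idx$counts)))
})

test_that("omitted-intersection concepts land in uncovered under strategy none", {
  idx <- published_index_d10
  cssn <- build_cssn(idx, fx, build_config(30, "none"))
  omitted <- names(idx$counts)[sig_size(names(idx$counts)) > 1L &
                                 idx$counts < 30]
  expect_setequal(cssn$uncovered,
                  unlist(idx$extents[omitted], use.names = FALSE))
  # with N = 1 nothing is uncovered and assignment is total
  full <- build_cssn(idx, fx, build_config(1, "none"))
  expect_length(full$uncovered, 0L)
  expect_equal(nrow(full$assignment), sum(idx$counts))
})

test_that("a 3-intersection reproduces all four parent configurations", {
  trio <- c("T121", "T129", "T116")  # PS, IF, AAPP
  k12 <- sig_key(c("T121", "T129")); k13 <- sig_key(c("T121", "T116"))
  k23 <- sig_key(c("T129", "T116"))
  # (A) all three 2-subsets available -> exactly those three parents
  expect_setequal(derive_parents(trio, c(k12, k13, k23), fx),
                  c(k12, k13, k23))
  # (B) two 2-subsets available -> exactly those two
  expect_setequal(derive_parents(c("Pharmacologic Substance",
                                   "Hazardous or Poisonous Substance",
                                   "Organic Chemical"),
                                 c(key_of("Hazardous or Poisonous Substance",
                                          "Organic Chemical"),
                                   key_of("Pharmacologic Substance",
                                          "Organic Chemical")),
                                 fx),
                  c(key_of("Hazardous or Poisonous Substance", "Organic Chemical"),
                    key_of("Pharmacologic Substance", "Organic Chemical")))
  # (C) one 2-subset available -> that pair plus the leftover singleton
  expect_setequal(derive_parents(c("Pharmacologic Substance", "Steroid",
                                   "Hormone"),
                                 key_of("Pharmacologic Substance", "Steroid"),
                                 fx),
                  c(key_of("Pharmacologic Substance", "Steroid"),
                    st_tui(fx, "Hormone")))
  # (D) no 2-subset available -> the three singletons
  expect_setequal(derive_parents(trio, character(0), fx), sort(trio))
})

test_that("a 2-intersection has exactly its two pure-type parents", {
  expect_setequal(derive_parents(c("Organic Chemical", "Pharmacologic Substance"),
                                 character(0), fx),
                  tui_of("Organic Chemical", "Pharmacologic Substance"))
})

test_that("parent derivation equals the brute-force maximal-subset oracle", {
  pool <- tui_of("Organic Chemical", "Pharmacologic Substance",
                 "Immunologic Factor", "Hormone", "Steroid", "Antibiotic")
  withr::with_seed(7, {
    for (rep in 1:40) {
      members <- sample(pool, sample(2:6, 1))
      # random availability: a random subset of all proper multi-subsets
      all_sub <- unlist(lapply(2:(length(members) - 1), function(k) {
        if (k > length(members) - 1) return(NULL)
        utils::combn(sort(members), k, paste, collapse = "+")
      }))
      avail <- if (length(all_sub)) {
        sample(all_sub, stats::rbinom(1, length(all_sub), 0.4))
      } else character(0)
      expect_equal(sort(derive_parents(members, avail, fx)),
                   oracle_parents(members, avail),
                   info = paste(sig_key(members), "|", paste(avail, collapse = " ")))
    }
  })
})

test_that("the IS-A graph is a DAG with the required local structure", {
  for (seed in c(21, 22)) {
    idx <- rand_index(500, seed = seed)
    cssn <- build_cssn(idx, fx, build_config(3, "none"))
    edges <- cssn$edges
    # an intersection's parent is always a proper subset of it
    ist_edges <- edges[sig_size(edges$child) > 1L, ]
    expect_true(all(mapply(function(c, p) {
      all(sig_members(p) %in% sig_members(c)) &&
        length(sig_members(p)) < length(sig_members(c))
    }, ist_edges$child, ist_edges$parent)))
    # acyclic by construction (edges reduce signature size or follow the tree);
    # ISTs have >= 2 parents whose signatures union to the child's
    ist <- cssn$types[cssn$types$kind == "IST", ]
    for (k in ist$key) {
      ps <- edges$parent[edges$child == k]
      expect_gte(length(ps), 2L)
      expect_setequal(unique(unlist(lapply(ps, sig_members))), sig_members(k))
    }
    # PST edges are a bijection with the semantic network's subtree edges
    pst_edges <- edges[sig_size(edges$child) == 1L, ]
    expect_equal(nrow(pst_edges), nrow(fx$edges))
    expect_setequal(paste(pst_edges$child, pst_edges$parent),
                    paste(fx$edges$child, fx$edges$parent))
  }
})

test_that("build matches an end-to-end brute-force reimplementation", {
  pairs <- rand_pairs(1000, seed = 31)
  tab <- restrict_to_chemical(pairs, CHEM)
  idx <- build_index(tab)
  cssn <- build_cssn(idx, fx, build_config(5, "largest"))
  expect_equal(nrow(cssn$assignment), tab$n_concepts)

  # independent re-derivation from the raw pairs
  oracle <- oracle_index(pairs, CHEM)
  counts <- lengths(oracle)
  type_keys <- union(CHEM, names(counts)[lengths(strsplit(names(counts),
                                                          "+", fixed = TRUE)) >= 2 &
                                           counts >= 5])
  got <- stats::setNames(cssn$assignment$key, cssn$assignment$cui)
  for (k in names(oracle)) {
    expected_key <- if (k %in% type_keys) k else {
      cand <- oracle_parents(strsplit(k, "+", fixed = TRUE)[[1]], type_keys)
      sizes <- counts[cand]; sizes[is.na(sizes)] <- 0L
      nm <- vapply(cand, function(x) paste(sort(st_name(fx, sig_members(x))),
                                           collapse = ""), character(1))
      cand[order(-sizes, -lengths(strsplit(cand, "+", fixed = TRUE)), nm)][[1]]
    }
    expect_true(all(got[oracle[[k]]] == expected_key), info = k)
  }
})

test_that("coverage is the exact-signature fraction, strategy-independent", {
  idx <- published_index_d10
  expect_equal(cssn_coverage(build_cssn(idx, fx, build_config(1, "none"))), 1.0)
  c_none <- cssn_coverage(build_cssn(idx, fx, build_config(30, "none")))
  c_rel <- cssn_coverage(build_cssn(idx, fx, build_config(30, "relax")))
  expect_equal(c_none, c_rel)
  # hand count: the only sub-threshold signatures at this scale
  omitted <- names(idx$counts)[sig_size(names(idx$counts)) > 1 & idx$counts < 30]
  expect_equal(c_none, 1 - sum(idx$counts[omitted]) / sum(idx$counts))
})

test_that("sweep rows are ordered as given with non-increasing size and coverage", {
  idx <- published_index_d10
  sw <- threshold_sweep(idx, fx, c(50, 30, 10, 5, 1))
  expect_equal(sw$N, c(50L, 30L, 10L, 5L, 1L))
  expect_equal(sw$coverage[sw$N == 1], 1.0)
  for (seed in c(41, 42, 43)) {
    idx2 <- rand_index(400, seed = seed)
    sw2 <- threshold_sweep(idx2, fx, c(1, 2, 5, 10, 50))
    expect_true(all(diff(sw2$type_count) <= 0))
    expect_true(all(diff(sw2$coverage) <= 1e-12))
  }
})
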