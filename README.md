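# cssn: Chemical Specialty Semantic Networks from UMLS semantic-type assignments

In the UMLS, the Semantic Network (SN) categorises every Metathesaurus
concept with one or more of ~135 broad semantic types (STs). In the chemical
subtree this deliberately produces multi-typing — almost every chemical
concept carries one type from the *structural* axis (e.g. **Organic
Chemical**) and at least one from the *functional* axis (e.g. **Pharmacologic
Substance**) — so the extent of a single ST mixes concepts with quite
different combined semantics. `cssn` derives a **Chemical Specialty Semantic
Network (CSSN)**: a finer-grained type system whose types are *mutually
exclusive* and semantically uniform, built automatically from the existing ST
inventory and the existing concept–ST assignment table. It is aimed at
terminologists and ontology engineers who audit ST assignments, need a
pre-coordinated guide for typing new chemical concepts, or want a compact
upper-level network for mapping chemical ontologies (e.g. ChEBI) onto UMLS
source vocabularies.

## The method

Write `sig(c)` for the **signature** of concept `c`: the exact set of
chemical STs assigned to it (non-chemical STs are dropped; concepts with no
chemical ST are out of scope). Signatures induce a partition of the chemical
concepts:

- each singleton signature `{A}` is reified as a **pure semantic type
  (PST)** `A`, present for all 25 chemical STs regardless of extent;
- each observed combination `{A, B, …}` with two or more STs is reified as an
  **intersection semantic type (IST)** `A ∩ B ∩ …` whose **extent** is the
  set of concepts with exactly that signature.

A threshold `N ≥ 1` controls granularity: an IST enters the CSSN only if its
extent has at least `N` concepts (`N` never applies to PSTs). Concepts whose
IST was omitted are either left uncovered, added to the *largest-extent*
maximal sub-signature that survived, or *relaxed*: STs in the signature are
generalised stepwise to their SN parents (functional axis first, deepest type
first, duplicates merged) until the current signature exists in the network.
IS-A links are derived, not curated: a PST mirrors its ST's SN link, and the
parents of an IST `s` are the maximal elements, under set inclusion, of the
available signatures strictly contained in `s` — which is why an IST always
has at least two parents and the union of its parents' signatures equals its
own. Display names are produced by a priority ordering (general-purpose
functional < structural < specific functional, rightmost component highest),
with unessential words dropped: `{Pharmacologic Substance, Steroid, Hormone}`
renders as "Pharmacologic Steroid Hormone".

## Worked example

The package bundles the 25-type chemical subtree of the 2009AA Semantic
Network and a synthetic assignment-table spec carrying the published extent
sizes, so no licensed UMLS download is needed. At one-tenth scale
(`divisor = 10`, so the published `N = 300` corresponds to `N = 30`):

```r
library(cssn)
net <- chem_fixture()
lines <- generate_assignments(published_extent_spec(divisor = 10), net)
tab <- restrict_to_chemical(read_mrsty(lines), subtree(net, "Chemical"))
idx <- build_index(tab)
cssn <- build_cssn(idx, net, build_config(threshold = 30, strategy = "relax"))
cssn
#> Chemical Specialty Semantic Network (threshold N = 30, strategy = relax)
#>   33 types: 25 pure + 8 intersection; 41 IS-A edges
#>   23611 concepts assigned (43 by reassignment), 0 uncovered; exact coverage 99.8%
```

33 types = 25 PSTs plus the 8 ISTs whose scaled extents reach 30; the 43
reassigned concepts are those of the two sub-threshold ISTs, relocated by
relaxation, so nothing is left uncovered. The indented listing shows extents
and derived names (one `*` per parent beyond the displayed one):

```r
head(cssn_listing(cssn)[, c("size", "text")], 6)
#>  size                                                        text
#>     2                                                    Chemical
#>    24                                Chemical Viewed Structurally
#>  5834                                            Organic Chemical
#>  7683                             *Pharmacologic Organic Chemical
#>   415                       *Biologically Active Organic Chemical
#>    50         *Pharmacologic Biologically Active Organic Chemical
```

Sweeping the threshold exposes the size-versus-coverage tradeoff, and a
relaxation trace explains an individual reassignment:

```r
threshold_sweep(idx, net, c(50, 30, 10, 5, 1))
#>   N type_count coverage
#>  50         32    99.6%
#>  30         33    99.8%
#>  10         35   100.0%
#>   5         36   100.0%
#>   1         36   100.0%

reassign_relax(c("Organic Chemical", "Hormone", "Immunologic Factor"),
               cssn$types$key[cssn$types$kind == "IST"], net)
#> relaxation: T109+T125+T129 -> T109+T123 (2 steps)
#>   1. T125 -> T123  => T109+T123+T129
#>   2. T129 -> T123  => T109+T123
```

(coverage printed at one decimal; type counts at `N = 10` and `N = 5` differ
even where rounded coverage does not). The same pipeline is scriptable:

```sh
Rscript inst/scripts/cssn sweep --thresholds 50,30,10,5,1 --divisor 10
Rscript inst/scripts/cssn assign --signature "Organic Chemical;Hormone;Immunologic Factor" \
    --strategy relax --divisor 10 --explain
Rscript inst/scripts/cssn build --mrsty MRSTY.RRF --srdef SRDEF --srstr SRSTR --threshold 300
```

The last form reads a real UMLS release (licensed, not bundled).

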