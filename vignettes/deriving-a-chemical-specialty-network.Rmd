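---
title: "Deriving a chemical specialty semantic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a chemical specialty semantic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssn)
```

## The problem

The UMLS Semantic Network assigns broad semantic types (STs) to Metathesaurus
concepts, and in the chemical subtree multi-typing is the norm: a chemical is
usually typed once from the *structural* axis (what it is, e.g. **Steroid**)
and once or more from the *functional* axis (what it does, e.g.
**Pharmacologic Substance**, **Hormone**). The extent of any single ST
therefore mixes concepts with different combined semantics, which weakens the
network as an abstraction layer and as an auditing aid. The remedy
implemented here reifies each *exact combination* of chemical STs as a type
of its own, producing a Chemical Specialty Semantic Network (CSSN) whose
types are mutually exclusive and whose extents are semantically uniform.

## The model

Let `S` be the 25 STs of the subtree rooted at **Chemical**, and for each
concept `c` let `sig(c) ⊆ S` be its *signature*: the exact set of chemical
STs it carries after restriction.

* **Restriction.** Concepts carrying both chemical and non-chemical STs keep
  only the chemical ones (a soap typed Lipid + Manufactured Object is a
  chemical with signature `{Lipid}`); concepts with no chemical ST are out of
  scope. Restriction is idempotent and duplicate assignment rows are merged.
* **Types.** Every singleton `{A}` is a *pure semantic type* (PST); every
  observed `|sig| ≥ 2` is an *intersection semantic type* (IST) named
  `A ∩ B ∩ …`. Signatures partition the concepts, so type extents are
  pairwise disjoint by construction.
* **Threshold.** A CSSN is parameterised by an integer `N ≥ 1`: an IST is
  included only if its exact extent has at least `N` concepts. `N` never
  applies to PSTs, and all 25 PSTs are always instantiated — even with empty
  extents — so parent derivation and relaxation always have singleton
  fallbacks. Signatures of four or more STs are handled uniformly; nothing
  in the code special-cases 2- or 3-way intersections beyond display.
* **Coverage.** The coverage of a CSSN is the fraction of concepts whose
  exact signature survived as a type. We define it *before* any
  reassignment, which makes it independent of the relaxation strategy and
  analytically 100% at `N = 1`; it is the quantity traded off against network
  size when `N` grows.

## IS-A derivation

PST links mirror the Semantic Network exactly. The parents of an IST with
signature `s` are the *maximal* elements, under set inclusion, of the
available signatures strictly contained in `s`. Since every member's
singleton is always available, this yields at least two parents for any IST,
and the union of the parents' signatures always recovers `s`. For a 3-way
intersection the rule produces exactly four possible configurations —
three 2-ISTs; two 2-ISTs; one 2-IST plus a PST; three PSTs — depending on
which 2-subsets survived the threshold. Parents are recomputed *after*
threshold filtering, so dropping an IST can promote a PST into a parent role.
The test suite checks this rule against a brute-force subset-enumeration
oracle over all signatures of up to six STs.

## Reassignment of concepts from omitted types

With `N > 1` some concepts lose their exact type. Three behaviours are
offered (`build_config(strategy = …)`):

* `none` — the concepts are reported in `uncovered`; useful when measuring
  the coverage tradeoff itself.
* `largest` — each concept joins the candidate with the largest exact
  extent, candidates being the maximal available sub-signatures of its
  signature. Ties are broken by larger signature size, then by the
  lexicographically smaller tuple of sorted type names; the data give no
  guidance here and determinism is the only requirement.
* `relax` — the signature is generalised one step at a time: the deepest
  eligible ST is replaced by its SN parent, duplicates are merged, and
  availability is re-tested *immediately after every step* (this is what
  lets a 3-way signature stop at a valid 3-way generalisation instead of
  collapsing further). An IST is "available" when its extent reaches `N`;
  singletons are always available, with the root singleton as absorbing
  fallback, so the procedure is total and terminates — the summed
  depth-to-root of the signature strictly decreases each step.

Two genuinely open choices are worth recording. First, the *phase order*:
functional-axis types relax before structural ones. The published worked
traces only ever relax functional types while retaining the structural
assignment, and the functional group is introduced first in that use; we fix
that order and treat it as a documented convention. Second, *ties in depth*
(two equally deep relaxable STs, such as Hormone and Immunologic Factor,
both depth 3): the lexicographically smaller type name relaxes first. The
end result is unaffected in every case we know of — both orders merge into
the common parent — but the intermediate trace is defined by this rule.

## Naming

Intersection names are built from per-type *head* and *modifier* forms with
unessential words ("Substance", "Chemical") dropped from modifiers, shipped
as an editable TSV (`inst/extdata/name_rules.tsv`). Components are ordered
left to right by ascending priority class — general-purpose functional <
structural < specific functional — so the rightmost, highest-priority
component supplies the head: a Pharmacologic Steroid is first and foremost a
steroid. Ties within a class are ordered by SN tree number, not
alphabetically; this is what yields "Carbohydrate Lipid" and "Nucleic Acid,
Nucleoside, or Nucleotide Carbohydrate".

The split of functional types into "specific" and "general-purpose" is
inferred from the published example names, not defined anywhere; two types
are genuinely ambiguous. **Neuroreactive Substance or Biogenic Amine**
appears only *left* of a structural head, so the default table classes it
general-purpose functional. **Indicator, Reagent, or Diagnostic Aid** is
printed on *both* sides of structural heads in the published sample; the
default table keeps it specific functional, which reproduces two of the
three printed names, and the conflicting form ("Indicator, Reagent, or
Diagnostic Aid Amino Acid, Peptide, or Protein") is obtainable by editing
the rule table.

In indented listings a type is displayed under the single parent carrying
the rightmost components of its name (its *placement parent*), with one
asterisk per additional parent; within a pure type's block, intersections
are listed by descending extent, which matches the published listing.

## The synthetic generator

`signature_spec()`/`generate_assignments()` emit MRSTY-dialect tables with an
exact, seed-deterministic number of concepts per signature, including mixed
chemical/non-chemical rows; synthetic concept identifiers use a reserved
`S` prefix. `published_extent_spec()` encodes every extent size printed in the
study (the 25 pure-type extents and the twelve printed intersections,
including the one-concept Organic Chemical ∩ Hormone ∩ Immunologic Factor
combination), with a `divisor` for integer-scaled fast fixtures.

The generator emulates *signature structure only*. It reproduces exact
extent counts but not concept names, source vocabularies, or the long tail
of hundreds of small unprinted intersections present in a real release.
Tests passing on these tables therefore validate the derivation machinery —
partition, thresholding, DAG shape, reassignment, naming — not any claim
about counts in a licensed UMLS release; the full-scale headline numbers
require the real 2009AA files, which the command-line `build` accepts but
the package cannot bundle.

## Numerical and degenerate-input choices

* Thresholds are positive integers; `N = 1` is the identity (every observed
  signature survives, coverage exactly 1).
* Empty assignment tables yield empty indexes, a 25-type CSSN (PSTs only)
  and `NaN` coverage.
* Unknown STs in assignment rows are treated as non-chemical and dropped by
  restriction; unknown STs in signature specs are errors.
* Parsers are strict about record shape (field counts, duplicate
  identifiers, unresolvable names) and report line numbers; both ST names
  and TUIs are accepted wherever an ST is identified, with TUIs canonical.
* All randomness (synthetic tables, test case generation) runs under
  explicit seeds in private RNG scopes that never disturb the caller's
  random state.

## Problem sizes used by the checks

The bundled test suite exercises: 200 random 1,000-concept tables for the
partition/totality property; 25 random tables for threshold monotonicity;
all 57 signatures over a fixed 6-ST pool (with random availability sets)
against the brute-force parent oracle; and the full-scale published-extent
fixture (~235,000 concepts) for the worked reassignment examples and the
end-to-end build at the published threshold. These sizes were chosen as
representative desk-scale conditions for the derivation.

## Limitations

* The subtree fixture targets the 2009AA inventory; later releases changed
  the ST inventory and are untested.
* The disorders domain and other non-chemical subtrees are mechanically
  supported (`root` is configurable) but unvalidated.
* Curation workflows — provisional ISTs for incoming concepts, expert
  review of audit candidates — are out of scope; the audit report only
  surfaces candidates.
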