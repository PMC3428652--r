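Package: cssn
Title: Derive Chemical Specialty Semantic Networks from UMLS Semantic Type Assignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a Chemical Specialty Semantic Network (CSSN): a
    finer-grained, mutually exclusive type system over the chemical subtree of a
    UMLS-style Semantic Network. Concepts carrying several chemical semantic
    types are grouped by their exact type combination, each combination is
    reified as an intersection semantic type (IST), and ISTs whose extent falls
    below a configurable threshold are pruned, with two reassignment strategies
    (largest-extent choice and stepwise relaxation toward ancestor types) for
    the concepts they covered. Includes readers for the SRDEF/SRSTR/MRSTY.RRF
    pipe-delimited formats, IS-A DAG derivation by the maximal sub-combination
    rule, a priority-ordered type-naming engine, threshold sweep and audit
    reports, a synthetic assignment-table generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
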