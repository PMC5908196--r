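Package: lgtrecon
Title: Gene-Tree/Species-Tree Reconciliation and Lateral Gene Transfer Detection
Version: 0.9.0
Authors@R:
    person("LGT", "Reconciliation Team", email = "lgtrecon@example.org",
           role = c("aut", "cre"))
Description: Parsimony-based detection of lateral gene transfer (LGT) in gene
    families by duplication-transfer-loss (DTL) reconciliation of gene trees
    against a rooted species tree. Provides an undated DTL dynamic program
    with an exhaustive-enumeration oracle, a transfers-disallowed
    (duplication-loss) mode, support-threshold edge collapsing and minimum-cost
    polytomy resolution, a Robinson-Foulds/SPR cross-check of inferred
    transfers, homology-hit filtering, Tajima's D neutrality screening of
    phylogenomic markers, flanking-gene synteny scoring, gene-family count
    profiling (hierarchical clustering and PCA), seeded simulators of gene
    families with ground-truth event histories, neutral coalescent samples and
    shuffled gene neighborhoods, and an end-to-end classification pipeline
    that labels each family as vertical, lgt, unresolved or conflicting and
    summarizes donor lineages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
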