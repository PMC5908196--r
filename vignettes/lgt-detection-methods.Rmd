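---
title: "Detecting lateral gene transfer by DTL reconciliation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lateral gene transfer by DTL reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtrecon)
```

## The problem

A gene family whose tree disagrees with the species tree may owe that
discordance to gene duplication (D) followed by differential loss (L), or to
lateral gene transfer (T, also written LGT/HGT). `lgtrecon` implements the
parsimony framework used to separate these explanations in comparative
genomics of fungi: each rooted gene tree is embedded into a rooted species
tree and every embedding is priced by the events it implies. The family is
called laterally acquired only when (i) the optimal embedding uses at least
one transfer, (ii) it is strictly cheaper than the best transfer-free
(duplication--loss) embedding, and (iii) an independent topology-distance
check agrees that the discordance looks like a transplanted subtree. This
conservative conjunction mirrors the practice of requiring a second,
method-independent line of evidence before accepting a transfer.

## The undated DTL model

Write $\sigma$ for the mapping of gene-tree nodes to species-tree locations
(a location is a species-tree edge, identified with the node below it).
Speciations are free; a duplication costs $c_D$, a transfer $c_T$, a loss
$c_L$. Transfers are *undated*: a donor edge may send a copy to any edge
that is neither its ancestor nor its descendant, with no global time
consistency imposed. The optimum is computed by the standard dynamic program
over pairs (gene node, species location) with an "enter at the top of an
edge and descend, one loss per bypassed sibling" relaxation; complexity is
$O(|G|\,|S|^2)$ per family.

Three conventions deserve explicit statement:

* **Root origin.** The family is assumed ancestrally present at the species
  root, so losses along the path from the species root down to the mapping
  of the gene root *are charged*. This matches the package's own generative
  model (`simulate_dtl_family` starts a single lineage at the species root)
  and makes the worked three-taxon example below exact. The alternative
  convention (origin at the root mapping, no stem losses) lowers some
  optima: a family confined to one side of the root then pays nothing for
  its absence elsewhere. Both conventions order DTL and DL costs
  identically, because DL is DTL with $c_T = \infty$ under the same rule.
* **Canonical co-optimum.** Among minimum-cost solutions the one with the
  fewest transfers is returned (the cost and the transfer count are
  minimized lexicographically inside the dynamic program); remaining ties
  break by a fixed traversal preferring speciation > duplication > transfer.
  This makes every transfer call conservative and every run reproducible.
* **Transfer direction.** Parsimony prices a transfer identically in both
  directions, so the reported donor/recipient orientation of a single
  transfer is a canonical choice, not an inference. Donor summaries
  therefore treat a transfer as involving the focal clade if *either*
  endpoint touches it, and name the non-focal endpoint as the putative
  donor lineage.

The worked example: for the gene tree `((A,C),B)` on the species tree
`((A,B),C)` with costs $(c_D, c_T, c_L) = (1, 2, 1)$ the optimum is 3 (one
transfer, one loss); raising $c_T$ to 6 flips the optimum to 4 (one
duplication, three losses, no transfer). An exhaustive enumeration oracle
(`bruteforce_min_cost`, which scores every assignment of gene nodes to
species locations) certifies the dynamic program on all instances with at
most 7 leaves; the test suite checks agreement on 500 random instances at
transfer:duplication ratios 2, 4 and 6.

## Cost ratios and the classification rule

Duplication and loss costs are fixed at 1 and the transfer cost is the
transfer:duplication ratio, evaluated at ratios 2, 4 and 6; the smallest
ratio is *primary*. Ratio 2 is the most permissive setting at which a
transfer must still beat duplication-plus-two-losses; the higher ratios are
reported as a sensitivity band, and a family whose transfer count varies
across the band carries a `ratio_dependent` flag. Per family the pipeline:

1. collapses internal edges with support below 0.9 (strict `<`, so a
   support of exactly 0.9 survives; edges with no recorded support are kept,
   as consensus trees omit supports only at trivially resolved edges);
2. resolves any resulting polytomy into the binary arrangement minimizing
   DTL cost, by exhaustive search over the $(2d-3)!!$ arrangements up to
   degree 8;
3. reconciles at every ratio and once with transfers forbidden;
4. runs the SPR/RF cross-check (below) when the primary reconciliation
   contains transfers;
5. assigns the category: `unresolved` when the family contains only
   focal-clade sequences; `vertical` when the primary optimum has no
   transfers; `lgt` when transfers exist, DTL < DL strictly, and the scan
   proposes a focal-involving rearrangement; `conflicting` otherwise.

## The SPR/RF cross-check

The independent check asks whether the discordance looks like a small
number of transplanted subtrees. The gene tree is first restricted to one
tip per species -- the tip whose root path has the highest minimal support,
ties broken by gene id, since the distance is undefined with repeated
labels -- then midpoint-rooted and compared with the species tree by
symmetric difference. Because both trees are rooted at this point, the
comparison uses **rooted** clade sets rather than unrooted splits: a
transfer across the species-tree root moves the root of the gene tree and
is invisible to the unrooted distance (for three taxa the unrooted distance
is identically zero, which would make the check vacuous). Greedy
subtree-prune-and-regraft moves are then applied, each chosen to maximally
reduce the distance, stopping at distance zero, after five moves, or at a
local optimum. Each accepted move is a candidate transfer; it involves the
focal clade if the moved clade, its former sibling, or its destination does
(an SPR move is symmetric evidence, exactly as a parsimony transfer is
direction-ambiguous).

## Tajima's D and marker selection

Phylogenomic markers are screened for neutrality with Tajima's D,
$D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$, where $\hat\pi$ is the
mean pairwise difference over all $n(n-1)/2$ pairs and $S$ the number of
segregating sites; columns with gaps or more than two alleles are excluded
from both, per the infinite-sites assumptions. For $n = 3$ the variance
coefficients vanish identically ($c_1 = c_2 = 0$) while the numerator is
also exactly zero on binary data, and the implementation returns the limit
value 0 rather than an undefined sentinel; $S = 0$ or a vanishing variance
with a non-zero numerator returns `NA`. Significance uses the
beta-distribution approximation of the null (mean 0, variance 1 on the
theoretical $[D_{\min}, D_{\max}]$ for the sample size) with a two-sided
$\alpha = 0.05$ default -- the source analysis does not state its
acceptance rule, so this documented default is the package's choice. Marker
selection keeps genes that are syntenic in all genomes, have no off-target
protein above 50% amino-acid similarity (strictly greater excludes), and
classify neutral.

## Synteny scoring

Around an orthologous gene pair, the five flanking genes on each side are
compared: the score is the percentage of the ten positions whose orthologs
occur among the partner's flanks in conserved order, with order conservation
measured as the longest strictly increasing matching of positions.
Whether the original analysis scored order by exact positional identity or
by any order-preserving matching is not stated; the matching rule
generalizes the binary "all flanks orthologous and order conserved = 100%"
definition to the fractional scores it also reports, and an inversion
breaks order under it. Strand is ignored (the source describes order only).
A gene cluster counts as conserved when the mean per-gene percentage
strictly exceeds 80.

## What the simulators emulate -- and what they do not

`simulate_dtl_family` evolves a single lineage from the species root along
a depth-normalized ultrametric birth--death species tree; duplications,
transfers and losses fire as Poisson processes on branches, and a transfer
copies the lineage onto a uniformly chosen branch alive at the same moment
(on an ultrametric tree, contemporaneous branches are automatically
non-ancestral, so the generative model is time-consistent and strictly
stronger than the undated inference model -- conservative for power
estimates). Default rates are 0.1 per unit depth for all three events:
roughly one event per family on a 12-taxon tree, matching the sparse
histories (~0.5 inferred events per family) of the motivating data.
Every family carries its true event log, and an independent replay of that
log must reproduce the emitted gene tree exactly.

The simulators do **not** model sequence evolution, alignment error, or
inference noise in gene trees (supports are attached by
`perturb_supports`, not estimated), nor rate heterogeneity across branches.
A green simulation benchmark therefore establishes that the *decision
procedure* behaves correctly on known histories, not that tree estimation
from sequences is robust.

Two benchmarks anchor the pipeline's operating characteristics (12-taxon
tree, 4-species focal clade, fixed seeds):

* **False-positive control**: 200 families simulated with transfer rate 0
  must yield at most 5% `lgt` calls. Duplication-plus-loss histories can
  mimic a transfer in rare topologies; the DTL < DL requirement and the
  cross-check keep the measured rate at 0 in the shipped seeds.
* **Power control**: 200 families conditioned on *exactly one surviving
  transfer into the focal clade from a non-focal donor* (at most one copy
  per species, at least two non-focal species retained -- the unit of
  analysis mirrors orthologous groups, which is how the motivating study
  partitioned multi-copy families) must yield at least 70% `lgt` calls.
  The misses are informative: transfers from the focal clade's sister
  lineage are topologically invisible, and transfers that only shift the
  gene root are rejected by design when the rooted cross-check cannot
  confirm them.

## Numerical and degenerate-input choices

* Percentages are nearest-integer with halves rounded *up*
  (`round_half_up`), which reproduces every printed frequency of the
  motivating analysis (50/122 to 41%, ..., 43/122 to 35%); base R's
  round-half-to-even does not.
* Canonical Newick output orders children by smallest descendant label, so
  structurally equal trees serialize byte-identically; all tie-breaks in
  rooting, polytomy resolution and the SPR scan reduce to this order.
* Midpoint rooting breaks tied diameters by the lexicographically smallest
  leaf pair; since all diameter paths share the tree center the choice
  affects bookkeeping, not the root position.
* Families reduced to a single non-focal leaf reconcile trivially and are
  classified `vertical`; all-focal families are `unresolved` before any
  reconciliation; families whose every lineage died return an explicit
  empty-family sentinel, never a silent resample.
* The edge-support threshold collapses strictly below 0.9; contracted edge
  lengths are added to the children so leaf depths are preserved.

## Known limitations

Reconciliation assumes the gene tree is correct; weakly supported edges are
handled by collapse-and-re-resolve rather than by error models. The undated
transfer model can accept time-inconsistent event sets that a dated method
would reject. Donor assignment reports the smallest taxonomic rank covering
the donor edge's subtended species and cannot resolve donors at or above
the species-tree root. The greedy SPR scan is not an exact SPR-distance
computation; with the five-move budget it can stop at a local optimum and
under-report candidate transfers, which errs on the conservative side of
the `lgt` call.
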