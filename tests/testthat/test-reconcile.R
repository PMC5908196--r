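test_that("cost_scheme validates and records the ratio", {
  cs <- cost_scheme(1, 2, 1)
  expect_equal(cs$ratio, 2)
  expect_error(cost_scheme(0, 2, 1), "> 0")
  expect_error(cost_scheme(1, -1, 1), "> 0")
  expect_silent(cost_scheme(1, Inf, 1))
})

test_that("congruent single-copy families reconcile at zero cost", {
  sp <- sp3()
  gt <- parse_newick("((A,B),C);", "gene")
  for (f in list(dtl_reconcile, dl_reconcile)) {
    rec <- f(gt, sp)
    expect_equal(rec$cost, 0)
    expect_equal(rec$n_transfer + rec$n_duplication + rec$n_loss, 0L)
    expect_equal(sum(rec$events$kind == "speciation"), 2L)
  }
})

test_that("the worked discordant family matches exhaustive enumeration", {
  sp <- sp3()
  gt <- parse_newick("((A,C),B);", "gene")
  r2 <- dtl_reconcile(gt, sp, cost_scheme(1, 2, 1))
  expect_equal(r2$cost, 3)
  expect_equal(r2$n_transfer, 1L)
  expect_equal(r2$n_loss, 1L)
  expect_equal(bruteforce_min_cost(gt, sp, cost_scheme(1, 2, 1)), 3)
  r6 <- dtl_reconcile(gt, sp, cost_scheme(1, 6, 1))
  expect_equal(r6$cost, 4)
  expect_equal(r6$n_transfer, 0L)
  expect_equal(bruteforce_min_cost(gt, sp, cost_scheme(1, 6, 1)), 4)
  dl <- dl_reconcile(gt, sp)
  expect_equal(dl$cost, 4)
  expect_equal(dl$n_duplication, 1L)
  expect_equal(dl$n_loss, 3L)
})

test_that("a within-species duplication is one duplication plus stem loss", {
  # the family spans only the (A,B) side, so the unused C lineage is charged
  # as a loss under the root-origin convention
  sp <- sp3()
  gt <- parse_newick("((A@1,A@2),B@1);", "gene")
  rec <- dtl_reconcile(gt, sp, cost_scheme(1, 2, 1))
  expect_equal(rec$cost, bruteforce_min_cost(gt, sp, cost_scheme(1, 2, 1)))
  expect_equal(rec$cost, 2)
  expect_equal(rec$n_duplication, 1L)
  expect_equal(rec$n_loss, 1L)
  expect_equal(rec$mapping[["mrca(A@1,A@2)"]], "A")
})

test_that("reconciliation rejects invalid inputs with useful messages", {
  sp <- sp3()
  expect_error(dtl_reconcile(parse_newick("((A,X),B);", "gene"), sp),
               "X")
  un <- parse_newick("(A,B,C);", "gene")
  expect_error(dtl_reconcile(un, sp), "optimal_root")
  poly <- parse_newick("((A,B,C),B@2);", "gene")
  attr(poly, "unrooted") <- FALSE
  expect_error(dtl_reconcile(poly, sp), "resolve_polytomies")
})

test_that("dtl_reconcile equals the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    for (tc in c(2, 4, 6)) {
      cs <- cost_scheme(1, tc, 1)
      rec <- dtl_reconcile(inst$gene, inst$species, cs)
      expect_equal(rec$cost, bruteforce_min_cost(inst$gene, inst$species, cs),
                   info = paste("seed", seed, "ratio", tc))
      expect_silent(check_reconciliation(rec, inst$gene, inst$species))
    }
  }
})

test_that("costs are monotone and transfers decrease with the ratio", {
  for (seed in 1:25) {
    inst <- random_instance(seed + 100)
    base <- dtl_reconcile(inst$gene, inst$species, cost_scheme(1, 2, 1))
    # raising any single event cost never lowers the optimum
    for (cs in list(cost_scheme(2, 2, 1), cost_scheme(1, 3, 1),
                    cost_scheme(1, 2, 2))) {
      expect_gte(dtl_reconcile(inst$gene, inst$species, cs)$cost, base$cost)
    }
    # transfer count non-increasing over ratios 2, 4, 6
    tr <- vapply(c(2, 4, 6), function(r)
      dtl_reconcile(inst$gene, inst$species,
                    cost_scheme(1, r, 1))$n_transfer, integer(1))
    expect_true(all(diff(tr) <= 0L))
    # DL is the restriction of DTL
    dl <- dl_reconcile(inst$gene, inst$species)
    expect_gte(dl$cost, base$cost)
    expect_equal(dl$n_transfer, 0L)
    # transfer cost Inf reduces DTL to DL exactly
    expect_equal(dtl_reconcile(inst$gene, inst$species,
                               cost_scheme(1, Inf, 1))$cost, dl$cost)
  }
})

test_that("optimal_root recovers a zero-cost rooting of a congruent tree", {
  sp <- parse_newick("(((A,B),C),D);", "species")
  un <- parse_newick("(A,B,(C,D));", "gene")  # unrooted version
  rooted <- optimal_root(un, sp)
  expect_equal(dtl_reconcile(rooted, sp)$cost, 0)
})

test_that("optimal_root attains the minimum over all rootings", {
  for (seed in 1:10) {
    set.seed(seed)
    phy <- ape::rtree(4, tip.label = paste0(c("A", "B", "C", "D"), "@1"))
    phy$node.label <- NULL
    un <- ape::unroot(phy)
    gene <- parse_newick(write_newick(un), "gene")
    sp <- parse_newick("(((A,B),C),D);", "species")
    best <- optimal_root(gene, sp)
    best_cost <- dtl_reconcile(best, sp)$cost
    # oracle: enumerate every rooting explicitly
    all_costs <- vapply(lgtrecon:::all_rootings(gene), function(nested) {
      phy2 <- lgtrecon:::restore_gene_tree(
        lgtrecon:::nested_to_phylo(nested), gene)
      dtl_reconcile(phy2, sp)$cost
    }, numeric(1))
    expect_equal(best_cost, min(all_costs))
    # determinism
    expect_identical(write_newick(best), write_newick(optimal_root(gene, sp)))
  }
})

test_that("resolve_polytomies searches all resolutions", {
  sp <- sp3()
  binary <- parse_newick("((A,B),C);", "gene")
  expect_identical(write_newick(resolve_polytomies(binary, sp)),
                   write_newick(binary))
  star <- parse_newick("(A,B,C);", "gene")
  attr(star, "unrooted") <- FALSE
  res <- resolve_polytomies(star, sp)
  expect_identical(write_newick(lgtrecon:::strip_lengths_phylo(res)),
                   "((A,B),C);")
  expect_equal(dtl_reconcile(res, sp)$cost, 0)
  # cap enforcement on a degree-9 polytomy
  big <- parse_newick(paste0("(", paste0("t", 1:9, collapse = ","), ");"),
                      "gene")
  attr(big, "unrooted") <- FALSE
  bigsp <- parse_newick(write_newick(ape::rtree(9,
    tip.label = paste0("t", 1:9))), "species")
  expect_error(resolve_polytomies(big, bigsp), "max_degree")
})

test_that("replaying any returned reconciliation is consistent", {
  for (seed in 1:15) {
    inst <- random_instance(seed + 300)
    for (f in list(dtl_reconcile, dl_reconcile)) {
      rec <- f(inst$gene, inst$species)
      expect_silent(check_reconciliation(rec, inst$gene, inst$species))
      implied <- rec$n_duplication * rec$costs$dup +
        rec$n_loss * rec$costs$loss +
        rec$n_transfer * (if (is.finite(rec$costs$transfer))
          rec$costs$transfer else 0)
      expect_equal(implied, rec$cost)
    }
  }
})

test_that("bruteforce oracle enforces its size limit and monotonicity", {
  sp8 <- parse_newick(write_newick(ape::rtree(8,
    tip.label = paste0("x", 1:8))), "species")
  g8 <- parse_newick(write_newick(ape::rtree(8,
    tip.label = paste0("x", 1:8, "@1"))), "gene")
  expect_error(bruteforce_min_cost(g8, sp8), "7 leaves")
  inst <- random_instance(999)
  base <- bruteforce_min_cost(inst$gene, inst$species, cost_scheme(1, 2, 1))
  expect_gte(bruteforce_min_cost(inst$gene, inst$species,
                                 cost_scheme(1.5, 2, 1)), base)
  expect_gte(bruteforce_min_cost(inst$gene, inst$species,
                                 cost_scheme(1, 2.5, 1)), base)
  expect_gte(bruteforce_min_cost(inst$gene, inst$species,
                                 cost_scheme(1, 2, 1.5)), base)
})
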