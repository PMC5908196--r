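test_that("filter_homologs applies strict coverage and E-value cutoffs", {
  hits <- data.frame(query = "q", subject = paste0("s", 1:4),
                     coverage = c(0.95, 0.90, 0.95, 0.91),
                     evalue = c(1e-120, 1e-120, 1e-100, 0))
  kept <- filter_homologs(hits)
  expect_identical(kept$subject, c("s1", "s4"))  # 0.90 and 1e-100 both drop
  expect_identical(filter_homologs(hits[0, ])$subject, character(0))
  expect_error(filter_homologs(data.frame(coverage = 2, evalue = 1)),
               "\\[0, 1\\]")
})

test_that("dedupe_by_species removes within-species duplicates only", {
  rec <- data.frame(id = paste0("r", 1:5),
                    species = c("X", "X", "Y", "X", "Y"),
                    sequence = c("MKV", "MKV", "MKV", "MLL", "MKV"))
  out <- dedupe_by_species(rec)
  expect_identical(out$id, c("r1", "r3", "r4"))  # r2 dup of r1; r5 of r3
  all_unique <- data.frame(species = c("X", "Y"), sequence = c("A", "A"))
  expect_identical(dedupe_by_species(all_unique), all_unique)
})

test_that("spr_transfer_scan resolves the worked 3-taxon discordance", {
  sp <- sp3()
  congruent <- parse_newick("((A,B),C);", "gene")
  expect_length(spr_transfer_scan(congruent, sp)$moves, 0L)
  scan <- spr_transfer_scan(parse_newick("((A,C),B);", "gene"), sp)
  expect_length(scan$moves, 1L)
  expect_equal(scan$final_rf, 0L)
  # move budget 0 reports the unresolved distance
  capped <- spr_transfer_scan(parse_newick("((A,C),B);", "gene"), sp,
                              max_moves = 0L)
  expect_length(capped$moves, 0L)
  expect_false(capped$resolved)
  expect_gt(capped$start_rf, 0L)
})

test_that("the scan prunes multi-copy trees to the best-supported tip", {
  sp <- sp3()
  # A@2 hangs discordantly next to C with weak support; A@1 sits in the
  # well-supported congruent position and must be the tip retained
  g <- parse_newick("(((A@1:1,B@1:1)1.0:1,(A@2:1,C@1:1)0.4:1)1.0:1,C@2:3);",
                    "gene")
  pruned <- lgtrecon:::prune_to_one_tip_per_species(g)
  expect_setequal(pruned$tip.label, c("A", "B", "C"))
})

test_that("classify_family reproduces the worked categories", {
  sp <- sp3()
  congruent <- parse_newick("((A,B),C);", "gene")
  cl <- classify_family(congruent, sp, focal_clade = "C")
  expect_identical(cl$category, "vertical")
  expect_true(all(cl$per_ratio$transfers == 0L))

  disc <- parse_newick("((A,C),B);", "gene")
  cl2 <- classify_family(disc, sp, focal_clade = "C")
  expect_identical(cl2$category, "lgt")
  expect_equal(cl2$per_ratio$transfers, c(1L, 0L, 0L))  # ratio 2 only
  expect_equal(cl2$per_ratio$dtl_cost, c(3, 4, 4))
  expect_equal(cl2$per_ratio$dl_cost[1], 4)
  expect_true(cl2$ratio_dependent)

  only_focal <- parse_newick("((C@1,C@2),C@3);", "gene")
  cl3 <- classify_family(only_focal, sp, focal_clade = "C")
  expect_identical(cl3$category, "unresolved")
  expect_true(all(is.na(cl3$per_ratio$transfers)))
})

test_that("classification is deterministic", {
  sp <- benchmark_species()
  focal <- benchmark_focal(sp)
  f <- conditioned_transfer_families(sp, focal, 1)[[1]]
  a <- classify_family(f$tree, sp, focal_clade = focal)
  b <- classify_family(f$tree, sp, focal_clade = focal)
  expect_identical(a$category, b$category)
  expect_identical(a$per_ratio, b$per_ratio)
  expect_identical(a$donor, b$donor)
})

test_that("lgt calls are non-increasing in the primary ratio", {
  sp <- benchmark_species()
  focal <- benchmark_focal(sp)
  fams <- conditioned_transfer_families(sp, focal, 12)
  calls <- vapply(c(2, 4, 6), function(r) {
    sum(vapply(fams, function(f)
      classify_family(f$tree, sp, focal_clade = focal,
                      ratios = c(r, 6))$per_ratio$transfers[1] > 0L,
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("assign_donor names the smallest covering rank", {
  taxonomy <- data.frame(
    species = c("A", "B", "C", "D"),
    genus = c("ga", "gb", "gc", "gd"),
    order = c("o1", "o1", "o2", "o2"),
    class = c("k1", "k1", "k1", "k1"))
  sp <- parse_newick("(((A,B),C),D);", "species")
  # terminal donor edge -> that species
  gt <- parse_newick("(((A,D@2),B),(C,D@1));", "gene")
  rec <- dtl_reconcile(gt, sp, cost_scheme(1, 2, 1))
  expect_gte(rec$n_transfer, 1L)
  don <- assign_donor(rec, sp, taxonomy)
  expect_gte(length(don), 1L)
  # synthetic reconciliation rows exercise the rank walk directly
  fake <- list(events = data.frame(
    kind = "transfer", gene_node = "g", location = "mrca(A,B)",
    donor = c("mrca(A,B)", "mrca(A,B,C,D)", "A"),
    recipient = c("D", "D", "D")))
  class(fake) <- "reconciliation"
  don2 <- assign_donor(fake, sp, taxonomy)
  expect_identical(don2, c("order:o1", "unresolved (root)", "A"))
  expect_error(assign_donor(fake, sp, taxonomy[1:2, ]), "lacks species")
})

test_that("summarize_classification reproduces printed arithmetic", {
  sm <- summarize_classification(counts = c(lgt = 50, vertical = 29,
                                            unresolved = 13,
                                            conflicting = 28, other = 2))
  expect_equal(sm$total, 122)
  expect_equal(unname(sm$percentages[c("lgt", "vertical", "unresolved",
                                       "conflicting")]),
               c(41, 24, 11, 23))
  expect_equal(sum(sm$counts), sm$total)
  expect_lte(abs(sum(sm$percentages) - 100), 2)
  sm2 <- summarize_classification(counts = c(lgt = 3, vertical = 1))
  expect_equal(unname(sm2$percentages), c(75, 25))
  expect_error(summarize_classification(list()), "no classifications")
  # from classification objects, with donor tally
  cls <- list(
    structure(list(category = "lgt", donor = "order:o1"),
              class = "family_classification"),
    structure(list(category = "lgt", donor = "order:o1"),
              class = "family_classification"),
    structure(list(category = "vertical", donor = character(0)),
              class = "family_classification"))
  sm3 <- summarize_classification(cls)
  expect_equal(unname(sm3$counts[c("lgt", "vertical")]), c(2L, 1L))
  expect_equal(unname(sm3$percentages[["lgt"]]), 67)
  expect_identical(sm3$donors$donor, "order:o1")
  expect_identical(sm3$donors$n, 2L)
})

test_that("round_half_up reproduces every printed percentage", {
  printed <- c(50, 29, 13, 28, 80, 43)
  expect_equal(round_half_up(100 * printed / 122), c(41, 24, 11, 23, 66, 35))
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)       # base round() would give 2
  expect_equal(round_half_up(1.25, 1), 1.3)
})
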