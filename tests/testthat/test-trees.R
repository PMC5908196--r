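test_that("parse_newick reads minimal and annotated trees", {
  t1 <- parse_newick("(A,B);", "gene")
  expect_s3_class(t1, "gene_tree")
  expect_setequal(t1$tip.label, c("A", "B"))
  expect_true(all(is.na(lgtrecon:::numeric_node_labels(t1))))

  t2 <- parse_newick("((A:1,B:1)0.95:1,C:2);", "gene")
  sup <- lgtrecon:::numeric_node_labels(t2)
  expect_true(0.95 %in% sup)
  idx <- lgtrecon:::tree_index(t2)
  expect_equal(sort(idx$elen[1:3]), c(1, 1, 2))

  sp <- parse_newick("((A,B),C);", "species")
  expect_s3_class(sp, "species_tree")
})

test_that("parse_newick reports malformed input and bad labels", {
  expect_error(parse_newick("((A,B),C;", "gene"), "unclosed")
  expect_error(parse_newick("(A,B))C;", "gene"), "character 6")
  expect_error(parse_newick("(A,B)", "gene"), "terminal ';'")
  expect_error(parse_newick("((A,A),C);", "species"), "duplicate")
  expect_error(parse_newick("((A,B)2.5,C);", "gene"), "\\[0, 1\\]")
  expect_error(parse_newick("(A,B,C);", "species"), "binary|rooted")
})

test_that("write_newick is canonical and round-trips", {
  expect_equal(write_newick(parse_newick("(B,A);", "gene")), "(A,B);")
  s <- write_newick(parse_newick("((A:1,B:1)0.95:1,C:2);", "gene"))
  expect_match(s, "\\)0.95", fixed = FALSE)
  # structural equality => byte-identical output
  a <- parse_newick("((A:1,B:2)0.9:1,(C:1,D:1):2);", "gene")
  b <- parse_newick("((D:1,C:1):2,(B:2,A:1)0.9:1);", "gene")
  expect_identical(write_newick(a), write_newick(b))
  # parse(write(T)) == T on random trees
  for (seed in 1:10) {
    set.seed(seed)
    phy <- ape::rtree(sample(4:10, 1))
    phy$node.label <- NULL
    txt <- write_newick(parse_newick(write_newick(phy), "gene"))
    expect_identical(write_newick(parse_newick(txt, "gene")), txt)
  }
})

test_that("rf_distance matches the definition and the worked 4-leaf case", {
  t <- parse_newick("((A,B),(C,D));", "gene")
  expect_identical(rf_distance(t, t), 0L)
  u <- parse_newick("((A,C),(B,D));", "gene")
  expect_identical(rf_distance(t, u), 2L)
  expect_error(rf_distance(t, parse_newick("((A,B),(C,E));", "gene")),
               "D.*E|E.*D")
})

test_that("rf_distance is a metric and agrees with the phangorn oracle", {
  skip_if_not_installed("phangorn")
  trees <- lapply(1:9, function(seed) {
    set.seed(seed)
    phy <- ape::rtree(6, tip.label = paste0("t", 1:6))
    phy$node.label <- NULL
    phy
  })
  n <- length(trees)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    d[i, j] <- rf_distance(trees[[i]], trees[[j]])
    expect_lte(d[i, j], 2 * (6 - 3))                     # theoretical max
    expect_equal(d[i, j],
                 as.numeric(phangorn::RF.dist(trees[[i]], trees[[j]])))
  }
  expect_true(all(d == t(d)))                            # symmetry
  expect_true(all(diag(d) == 0))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)           # triangle
    expect_lte(d[i, k], d[i, j] + d[j, k])
})

test_that("midpoint_root places the root halfway along the diameter", {
  # two-leaf case: diameter 4, midpoint 2 from each leaf
  t <- midpoint_root(parse_newick("(A:1,B:3);", "gene"))
  idx <- lgtrecon:::tree_index(t)
  expect_equal(unname(idx$elen[1:2]), c(2, 2))
  # symmetric balanced tree: root stays at the original internal node
  bal <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);", "gene")
  expect_identical(write_newick(midpoint_root(bal)), write_newick(bal))
  expect_error(midpoint_root(parse_newick("((A,B),C);", "gene")),
               "unit-length")
})

test_that("midpoint_root handles tied diameters deterministically", {
  # caterpillar with tied diameters B-C and B-D (length 6); all diameter
  # paths share the tree center, and the lexicographic pair rule makes the
  # choice reproducible
  t <- parse_newick("(((A:1,B:3):1,C:2):1,D:1);", "gene")
  r1 <- midpoint_root(t)
  r2 <- midpoint_root(parse_newick("(D:1,(C:2,(B:3,A:1):1):1);", "gene"))
  expect_identical(write_newick(r1), write_newick(r2))
  # midpoint lies 3 units from B in both tied paths
  idx <- lgtrecon:::tree_index(r1)
  d <- ape::cophenetic.phylo(r1)
  expect_equal(max(d), 6)
})

test_that("midpoint_root agrees with phangorn on random trees", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    set.seed(seed)
    phy <- ape::rtree(sample(4:9, 1))
    phy$node.label <- NULL
    mine <- midpoint_root(phy)
    theirs <- phangorn::midpoint(phy)
    expect_identical(write_newick(lgtrecon:::strip_lengths_phylo(mine)),
                     write_newick(lgtrecon:::strip_lengths_phylo(theirs)))
  }
})

test_that("collapse_weak_edges contracts strictly below the threshold", {
  t <- parse_newick("((A,B)1.0,(C,D)1.0);", "gene")
  expect_identical(write_newick(collapse_weak_edges(t, 0.9)),
                   write_newick(t))
  t2 <- parse_newick("((A,B)0.5,C);", "gene")
  star <- collapse_weak_edges(t2, 0.9)
  expect_equal(star$Nnode, 1L)                   # star tree
  expect_setequal(star$tip.label, c("A", "B", "C"))
  # boundary: 0.9 survives (strict <), 0.89 goes
  t3 <- parse_newick("(((A,B)0.95,C)0.89,(D,E)0.9);", "gene")
  c3 <- collapse_weak_edges(t3, 0.9)
  expect_equal(c3$Nnode, t3$Nnode - 1L)
  expect_true("0.9" %in% c3$node.label)
  expect_false("0.89" %in% c3$node.label)
  # edges with no support are kept
  t4 <- parse_newick("((A,B),C);", "gene")
  expect_identical(write_newick(collapse_weak_edges(t4, 0.9)),
                   write_newick(t4))
})

test_that("collapse_weak_edges keeps the leaf set, never adds edges", {
  for (seed in 1:10) {
    set.seed(seed)
    phy <- ape::rtree(8)
    phy$node.label <- NULL
    g <- perturb_supports(parse_newick(write_newick(phy), "gene"),
                          weak_fraction = 0.5, seed = seed)
    g <- parse_newick(write_newick(g), "gene")
    out <- collapse_weak_edges(g, 0.9)
    expect_setequal(out$tip.label, g$tip.label)
    expect_lte(out$Nnode, g$Nnode)
  }
})
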