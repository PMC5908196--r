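# Shared fixtures and generators for the test suite. Everything is built in
# code; seeds are fixed so every run sees the same instances.

sp3 <- function() parse_newick("((A,B),C);", "species")

# random species tree + multi-copy gene tree pair for oracle-style tests
random_instance <- function(seed, max_tips = 6L) {
  set.seed(seed)
  ns <- sample(3:max_tips, 1L)
  species <- simulate_species_tree(ns, seed = seed)
  ng <- sample(3:max_tips, 1L)
  tips <- paste0(sample(species$tip.label, ng, replace = TRUE), "@",
                 seq_len(ng))
  gtr <- ape::rtree(ng, tip.label = tips)
  gtr$node.label <- NULL
  gene <- parse_newick(write_newick(gtr), "gene")
  list(species = species, gene = gene)
}

# the simulation benchmark world: 12 taxa, a mid-sized focal clade
benchmark_species <- function() simulate_species_tree(12, seed = 7)

benchmark_focal <- function(species = benchmark_species()) {
  sidx <- lgtrecon:::species_index(species)
  sizes <- vapply(sidx$postorder, function(v) length(sidx$clade[[v]]),
                  integer(1))
  cand <- sidx$postorder[sizes >= 3L & sizes <= 6L]
  pick <- cand[which.min(abs(vapply(cand, function(v)
    length(sidx$clade[[v]]), integer(1)) - 4L))]
  sidx$clade[[pick]]
}

# one family with exactly one surviving transfer into the focal clade from a
# non-focal donor, at most one copy per species, and at least two non-focal
# species retained (the unit of analysis mirrors orthologous groups);
# returns NULL when the seeded draw does not satisfy the conditions
conditioned_transfer_family <- function(species, focal, seed) {
  sidx <- lgtrecon:::species_index(species)
  f <- simulate_dtl_family(species,
                           sim_params(0.1, 0.3, 0.3, seed = seed))
  if (is_empty_family(f) || f$n_tip < 3L) return(NULL)
  ev <- f$events
  tr <- ev[ev$kind == "transfer", , drop = FALSE]
  if (nrow(tr) != 1L) return(NULL)
  rec_sp <- lgtrecon:::species_set_of(sidx, tr$recipient)
  don_sp <- lgtrecon:::species_set_of(sidx, tr$donor)
  if (!length(intersect(rec_sp, focal))) return(NULL)
  if (length(intersect(don_sp, focal))) return(NULL)
  spp <- lgtrecon:::gene_species(f$tree)
  if (any(table(spp) > 1L)) return(NULL)
  tip_lin <- as.integer(sub(".*@", "", names(spp)))
  lins <- c(tr$new_lineage, ev$new_lineage[ev$lineage %in% tr$new_lineage])
  if (!length(names(spp)[tip_lin %in% lins & spp %in% focal])) return(NULL)
  if (length(setdiff(spp, focal)) < 2L) return(NULL)
  f
}

# collect n conditioned families scanning seeds from 1 upward
conditioned_transfer_families <- function(species, focal, n,
                                          max_seeds = 60000L) {
  out <- list()
  s <- 0L
  while (length(out) < n && s < max_seeds) {
    s <- s + 1L
    f <- conditioned_transfer_family(species, focal, s)
    if (!is.null(f)) out[[length(out) + 1L]] <- f
  }
  out
}

# n transfer-free families (zero transfer rate), seeds from 1 upward
transfer_free_families <- function(species, n, max_seeds = 5000L) {
  out <- list()
  s <- 0L
  while (length(out) < n && s < max_seeds) {
    s <- s + 1L
    f <- simulate_dtl_family(species, sim_params(0.1, 0, 0.1, seed = s))
    if (!is_empty_family(f) && f$n_tip >= 2L)
      out[[length(out) + 1L]] <- f
  }
  out
}
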