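# Seeded generators for testable inputs: species trees, gene families with
# ground-truth duplication/transfer/loss histories, neutral coalescent
# polymorphism samples, and shuffled gene neighborhoods.

#' Simulation parameters for gene-family evolution
#'
#' Rates are per unit branch length on the depth-normalized species tree
#' (total depth 1). The defaults (0.1 each) put the simulator in the
#' sparse-event regime the reconciliation analysis assumes: on the order of
#' one event per family, comparable to the roughly 0.5 events per family
#' implied by ~50 transfers and ~12 duplications over 122 real families.
#'
#' @param dup_rate,transfer_rate,loss_rate non-negative event rates.
#' @param seed integer seed fixing all randomness.
#' @param focal_clade optional character vector of species ids whose gene
#'   origins are under study.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(dup_rate = 0.1, transfer_rate = 0.1, loss_rate = 0.1,
                       seed = 1L, focal_clade = NULL) {
  for (r in c(dup_rate, transfer_rate, loss_rate))
    if (!is_scalar_number(r) || r < 0) stop2("rates must be >= 0")
  structure(list(dup_rate = dup_rate, transfer_rate = transfer_rate,
                 loss_rate = loss_rate, seed = as.integer(seed),
                 focal_clade = focal_clade),
            class = "sim_params")
}

#' Simulate a rooted ultrametric species tree
#'
#' Birth-death process conditioned on `n_taxa` extant tips
#' (via [ape::rphylo()]), depth-normalized so the root-to-tip distance is 1.
#'
#' @param n_taxa number of tips (>= 3).
#' @param seed integer seed.
#' @param birth,death birth-death rates (defaults 1 and 0.3).
#' @return a `species_tree` with tips `s01`, `s02`, ...
#' @export
simulate_species_tree <- function(n_taxa, seed = 1L, birth = 1, death = 0.3) {
  if (!is_scalar_number(n_taxa) || n_taxa < 3)
    stop2("n_taxa must be at least 3")
  phy <- withr::with_seed(as.integer(seed),
                          ape::rphylo(n_taxa, birth, death, fossils = FALSE))
  phy$tip.label <- sprintf("s%02d", seq_len(n_taxa))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$node.label <- NULL
  class(phy) <- c("species_tree", "phylo")
  phy
}

# absolute time (distance from root) of every species node
species_times <- function(sidx) {
  tm <- numeric(sidx$n_node)
  for (v in rev(sidx$postorder)) if (sidx$parent[v] > 0L)
    tm[v] <- tm[sidx$parent[v]] + sidx$elen[v]
  tm
}

#' Simulate one gene family along a species tree with a true event history
#'
#' A single gene lineage enters at the species root. Along every species
#' branch, duplications, transfers and losses fire as independent Poisson
#' processes at the [sim_params()] rates. A transfer copies the lineage onto
#' a uniformly chosen branch alive at the same moment (contemporaneous
#' branches on an ultrametric tree are never ancestor and descendant);
#' lineages surviving to the leaves become gene-tree tips labelled
#' `species@lineage`. Speciations split lineages silently (they carry no
#' cost and are not logged).
#'
#' @param species an ultrametric `species_tree` (depth 1).
#' @param params a [sim_params()].
#' @return a list of class `dtl_family`: `tree` (a `gene_tree`, or `NULL`
#'   when every lineage was lost), `events` (the true history: kind, time,
#'   branch, donor, recipient, lineage, new_lineage) and `n_tip`.
#' @export
simulate_dtl_family <- function(species, params) {
  sidx <- species_index(species)
  tm <- species_times(sidx)
  rates <- c(params$dup_rate, params$transfer_rate, params$loss_rate)
  total_rate <- sum(rates)
  events <- list()
  lineage_counter <- 1L
  log_event <- function(kind, time, branch, donor, recipient, lin, new_lin) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, time = time, branch = node_name(sidx, branch),
      donor = if (is.na(donor)) NA_character_ else node_name(sidx, donor),
      recipient = if (is.na(recipient)) NA_character_ else
        node_name(sidx, recipient),
      lineage = lin, new_lineage = new_lin, stringsAsFactors = FALSE)
  }
  join <- function(a, b, t) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    nested_node(list(a, b), length = NA_real_)  # length set by parent
  }
  # lineage `lin` sits on the edge above species node v at time t0
  sim_branch <- function(v, t0, lin) {
    t_end <- tm[v]
    t <- t0
    repeat {
      dt <- if (total_rate > 0) stats::rexp(1L, total_rate) else Inf
      if (t + dt >= t_end) break
      t <- t + dt
      kind <- sample.int(3L, 1L, prob = rates)
      if (kind == 3L) {                      # loss
        log_event("loss", t, v, NA, NA, lin, NA_integer_)
        return(NULL)
      }
      if (kind == 1L) {                      # duplication
        lineage_counter <<- lineage_counter + 1L
        new_lin <- lineage_counter
        log_event("duplication", t, v, NA, NA, lin, new_lin)
        a <- sim_branch(v, t, lin)
        b <- sim_branch(v, t, new_lin)
        return(with_time(join(a, b, t), t, a, b))
      }
      # transfer: recipient drawn among branches alive at time t
      alive <- which(vapply(seq_len(sidx$n_node), function(w) {
        p <- sidx$parent[w]
        p > 0L && tm[p] < t && t < tm[w] && w != v
      }, logical(1)))
      if (!length(alive)) next               # no contemporaneous recipient
      w <- if (length(alive) == 1L) alive else
        alive[sample.int(length(alive), 1L)]
      lineage_counter <<- lineage_counter + 1L
      new_lin <- lineage_counter
      log_event("transfer", t, v, v, w, lin, new_lin)
      a <- sim_branch(v, t, lin)
      b <- sim_branch(w, t, new_lin)
      return(with_time(join(a, b, t), t, a, b))
    }
    # reached the end of the branch
    if (v <= sidx$n_tip) {
      tip <- nested_tip(paste0(sidx$tip_label[v], "@", lin))
      attr(tip, "time") <- t_end
      return(tip)
    }
    kids <- sidx$children[[v]]
    a <- sim_branch(kids[1L], t_end, lin)
    b <- sim_branch(kids[2L], t_end, lin)
    with_time(join(a, b, t_end), t_end, a, b)
  }
  with_time <- function(node, t, a, b) {
    if (is.null(node)) return(NULL)
    if (!is.null(a) && !is.null(b)) attr(node, "time") <- t
    node
  }
  nested <- withr::with_seed(params$seed, sim_branch(sidx$root, 0, 1L))
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), time = numeric(0), branch = character(0),
               donor = character(0), recipient = character(0),
               lineage = integer(0), new_lineage = integer(0),
               stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  build_family(nested, ev)
}

# turn the simulated nested lineage tree into a gene_tree (or sentinel)
build_family <- function(nested, ev) {
  if (is.null(nested))
    return(structure(list(tree = NULL, events = ev, n_tip = 0L),
                     class = "dtl_family"))
  set_lengths <- function(x, parent_time) {
    t <- attr(x, "time")
    x$length <- t - parent_time
    if (!is_nested_tip(x))
      x$children <- lapply(x$children, set_lengths, parent_time = t)
    x
  }
  root_time <- attr(nested, "time")
  nested <- set_lengths(nested, root_time %||% 0)
  labels <- nested_tip_labels(nested)
  if (length(labels) == 1L) {
    tree <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           tip.label = labels, Nnode = 1L,
                           edge.length = 1 - (root_time %||% 0)),
                      class = "phylo")
  } else {
    tree <- nested_to_phylo(canonicalize_nested(nested))
  }
  sp <- sub("@.*$", "", tree$tip.label)
  names(sp) <- tree$tip.label
  attr(tree, "species") <- sp
  attr(tree, "unrooted") <- FALSE
  class(tree) <- c("gene_tree", "phylo")
  structure(list(tree = tree, events = ev, n_tip = length(labels)),
            class = "dtl_family")
}

#' @rdname simulate_dtl_family
#' @param family a `dtl_family`.
#' @export
is_empty_family <- function(family) is.null(family$tree)

#' Independently replay a true event history
#'
#' Reconstructs the gene tree implied by a [simulate_dtl_family()] event log
#' without any random draws: lineages are propagated down the species tree,
#' consuming logged losses, duplications and transfers at their recorded
#' times and branches. Used to verify that the emitted gene tree and its
#' history agree exactly.
#'
#' @param events the `events` table of a `dtl_family`.
#' @param species the species tree the family was simulated on.
#' @return a `dtl_family`-like list with the replayed `tree`.
#' @export
replay_history <- function(events, species) {
  sidx <- species_index(species)
  tm <- species_times(sidx)
  sname <- vapply(seq_len(sidx$n_node), function(s) node_name(sidx, s),
                  character(1))
  sid <- stats::setNames(seq_len(sidx$n_node), sname)
  replay <- function(v, t0, lin) {
    cand <- events[events$lineage == lin & events$branch == sname[v] &
                     events$time > t0 + 1e-15 &
                     events$time < tm[v] - 1e-15, , drop = FALSE]
    if (nrow(cand)) {
      e <- cand[which.min(cand$time), , drop = FALSE]
      t <- e$time
      if (e$kind == "loss") return(NULL)
      new_lin <- e$new_lineage
      a <- replay(v, t, lin)
      b <- if (e$kind == "duplication") replay(v, t, new_lin) else
        replay(sid[[e$recipient]], t, new_lin)
      node <- if (is.null(a)) b else if (is.null(b)) a else
        nested_node(list(a, b))
      if (!is.null(node) && !is.null(a) && !is.null(b))
        attr(node, "time") <- t
      return(node)
    }
    if (v <= sidx$n_tip) {
      tip <- nested_tip(paste0(sidx$tip_label[v], "@", lin))
      attr(tip, "time") <- tm[v]
      return(tip)
    }
    kids <- sidx$children[[v]]
    a <- replay(kids[1L], tm[v], lin)
    b <- replay(kids[2L], tm[v], lin)
    node <- if (is.null(a)) b else if (is.null(b)) a else
      nested_node(list(a, b))
    if (!is.null(node) && !is.null(a) && !is.null(b))
      attr(node, "time") <- tm[v]
    node
  }
  build_family(replay(sidx$root, 0, 1L), events)
}

#' Randomly weaken internal edge supports
#'
#' Sets every internal edge support to 1.0, then downgrades a fraction of
#' them (rounded to the nearest count) to Uniform(0.3, 0.89) draws - i.e.
#' below the default 0.9 collapsing threshold.
#'
#' @param tree a gene tree.
#' @param weak_fraction fraction of internal edges to weaken, in `[0, 1]`.
#' @param seed integer seed.
#' @return the tree with supports assigned.
#' @export
perturb_supports <- function(tree, weak_fraction, seed = 1L) {
  assert_fraction(weak_fraction, "weak_fraction")
  n <- n_tips(tree)
  n_int <- tree$Nnode - 1L  # internal non-root nodes carry edge supports
  sup <- rep(1, tree$Nnode)
  if (n_int > 0L) {
    k <- round(weak_fraction * n_int)
    if (k > 0L) {
      pick <- withr::with_seed(as.integer(seed), list(
        which = sample.int(n_int, k),
        val = stats::runif(k, 0.3, 0.89)))
      sup[1L + pick$which] <- pick$val  # +1: first node label is the root
    }
  }
  tree$node.label <- num_fmt(sup)
  tree$node.label[1L] <- ""  # the root carries no edge
  tree
}

#' Simulate a neutral infinite-sites polymorphism sample
#'
#' Standard Kingman coalescent of `n` samples; mutations are dropped on
#' branches as Poisson(theta/2 x length) under the infinite-sites model,
#' producing one biallelic column per mutation.
#'
#' @param n sample size (>= 2).
#' @param theta population mutation rate (> 0).
#' @param seed integer seed.
#' @return a binary 0/1 matrix with `n` rows (haplotypes) and one column per
#'   segregating site (possibly zero columns).
#' @export
simulate_neutral_sites <- function(n, theta, seed = 1L) {
  if (!is_scalar_number(n) || n < 2) stop2("n must be >= 2")
  if (!is_scalar_number(theta) || theta <= 0) stop2("theta must be > 0")
  withr::with_seed(as.integer(seed), {
    n <- as.integer(n)
    members <- lapply(seq_len(n), identity)  # tip sets of active lineages
    blen <- numeric(n)                       # accumulated branch lengths
    cols <- list()
    while (length(members) > 1L) {
      k <- length(members)
      t_wait <- stats::rexp(1L, k * (k - 1) / 2)
      blen <- blen + t_wait
      pair <- sample.int(k, 2L)
      for (i in pair) {
        n_mut <- stats::rpois(1L, theta / 2 * blen[i])
        if (n_mut > 0L) {
          col <- integer(n)
          col[members[[i]]] <- 1L
          cols <- c(cols, rep(list(col), n_mut))
        }
      }
      merged <- c(members[[pair[1L]]], members[[pair[2L]]])
      members <- c(members[-pair], list(merged))
      blen <- c(blen[-pair], 0)
    }
    m <- if (length(cols)) do.call(cbind, cols) else
      matrix(integer(0), nrow = n, ncol = 0L)
    rownames(m) <- sprintf("h%02d", seq_len(n))
    m
  })
}

#' Simulate gene neighborhoods with controlled rearrangement
#'
#' Genome 1 carries the reference gene order `g001 ... gN`. Every other
#' genome starts from that order and applies `Binomial(n_genes,
#' shuffle_rate)` random operations, each an adjacent transposition (80%) or
#' a single-gene deletion (20%). The true ortholog map against the reference
#' is returned.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_genes genes per genome before deletions.
#' @param shuffle_rate per-gene operation rate in `[0, 1]`.
#' @param seed integer seed.
#' @return a list with `hoods` (named list of ordered gene-id vectors, one
#'   per genome `G1..Gk`) and `orthologs` (named list of two-column
#'   data.frames `a` = reference gene, `b` = genome gene, one per non-
#'   reference genome).
#' @export
simulate_neighborhoods <- function(n_genomes, n_genes, shuffle_rate,
                                   seed = 1L) {
  assert_fraction(shuffle_rate, "shuffle_rate")
  if (n_genomes < 2L) stop2("need at least 2 genomes")
  ref <- sprintf("g%03d", seq_len(n_genes))
  withr::with_seed(as.integer(seed), {
    hoods <- list(G1 = ref)
    orthos <- list()
    for (k in 2:n_genomes) {
      gid <- paste0("G", k)
      order_ref <- ref  # track which reference gene sits at each position
      n_ops <- stats::rbinom(1L, n_genes, shuffle_rate)
      for (op in seq_len(n_ops)) {
        if (length(order_ref) < 2L) break
        if (stats::runif(1L) < 0.8) {
          i <- sample.int(length(order_ref) - 1L, 1L)
          order_ref[c(i, i + 1L)] <- order_ref[c(i + 1L, i)]
        } else {
          i <- sample.int(length(order_ref), 1L)
          order_ref <- order_ref[-i]
        }
      }
      genes <- paste0(gid, "_", order_ref)
      hoods[[gid]] <- genes
      orthos[[gid]] <- data.frame(a = order_ref, b = genes,
                                  stringsAsFactors = FALSE)
    }
    list(hoods = hoods, orthologs = orthos)
  })
}
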