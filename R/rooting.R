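# Rooting and polytomy resolution driven by reconciliation cost.

# undirected adjacency of a phylo object: per node, list of (to, len, sup)
tree_adjacency <- function(phy) {
  idx <- tree_index(phy)
  nbr <- vector("list", idx$n_node)
  for (v in seq_len(idx$n_node)) nbr[[v]] <- list()
  for (v in seq_len(idx$n_node)) if (idx$parent[v] > 0L) {
    p <- idx$parent[v]
    e <- list(len = idx$elen[v], sup = idx$support[v])
    nbr[[p]][[length(nbr[[p]]) + 1L]] <- c(list(to = v), e)
    nbr[[v]][[length(nbr[[v]]) + 1L]] <- c(list(to = p), e)
  }
  list(idx = idx, nbr = nbr)
}

orient_nested <- function(adj, node, from) {
  kids <- Filter(function(e) e$to != from, adj$nbr[[node]])
  if (!length(kids)) return(nested_tip(adj$idx$tip_label[node]))
  nested_node(lapply(kids, function(e) {
    child <- orient_nested(adj, e$to, node)
    child$length <- e$len
    if (!is_nested_tip(child)) child$support <- e$sup
    child
  }))
}

# all rooted versions of a tree, one per unrooted edge (deduplicated)
all_rootings <- function(tree) {
  adj <- tree_adjacency(tree)
  idx <- adj$idx
  out <- list()
  seen <- character(0)
  for (v in seq_len(idx$n_node)) {
    p <- idx$parent[v]
    if (p == 0L) next
    len <- idx$elen[v]
    half <- if (is.na(len)) NA_real_ else len / 2
    left <- orient_nested(adj, v, p); left$length <- half
    right <- orient_nested(adj, p, v); right$length <- half
    if (!is_nested_tip(left)) left$support <- idx$support[v]
    if (!is_nested_tip(right)) right$support <- idx$support[v]
    rooted <- suppress_unary(nested_node(list(left, right)))
    rooted <- canonicalize_nested(rooted)
    key <- nested_to_newick(strip_lengths(rooted))
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- rooted
  }
  out
}

strip_lengths <- function(x) {
  x$length <- NA_real_
  x$children <- lapply(x$children, strip_lengths)
  x
}

reconcile_cost <- function(gene, species, costs, allow_transfer = TRUE) {
  gidx <- tree_index(gene)
  sidx <- species_index(species)
  gmap <- map_gene_tips(gene, sidx)
  tb <- dtl_tables(gidx, sidx, gmap, costs, allow_transfer)
  list(cost = tb$IN[gidx$root, sidx$root],
       transfers = tb$Tin[gidx$root, sidx$root])
}

#' Root an unrooted gene tree by minimizing DTL reconciliation cost
#'
#' Every edge of the unrooted gene tree is tried as a root position; the
#' rooting with the smallest [dtl_reconcile()] cost is returned. Ties are
#' broken by the lexicographically smallest leaf label under the first child
#' of the canonicalized rooting (then by the canonical topology string).
#'
#' @param gene a gene tree (typically flagged unrooted).
#' @param species rooted binary species tree.
#' @param costs a [cost_scheme()].
#' @return a rooted `gene_tree` attaining the minimum cost over all rootings.
#' @export
optimal_root <- function(gene, species, costs = cost_scheme()) {
  cands <- all_rootings(gene)
  best <- NULL
  for (nested in cands) {
    phy <- restore_gene_tree(nested_to_phylo(nested), gene)
    res <- reconcile_cost(phy, species, costs)
    key <- c(nested_min_tip(nested$children[[1L]]),
             nested_to_newick(strip_lengths(nested)))
    if (is.null(best) || res$cost < best$cost - 1e-9 ||
        (abs(res$cost - best$cost) <= 1e-9 &&
         (key[1L] < best$key[1L] ||
          (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
      best <- list(cost = res$cost, key = key, phy = phy)
    }
  }
  out <- best$phy
  attr(out, "unrooted") <- FALSE
  out
}

# all rooted binary arrangements of a list of subtrees (each kept intact);
# (2d-3)!! candidates for d subtrees
binary_arrangements <- function(items) {
  if (length(items) == 1L) return(list(items[[1L]]))
  trees <- list(items[[1L]])
  for (j in 2L:length(items)) {
    nxt <- list()
    for (tr in trees) {
      for (variant in insert_on_every_edge(tr, items[[j]]))
        nxt[[length(nxt) + 1L]] <- variant
    }
    trees <- nxt
  }
  trees
}

insert_on_every_edge <- function(tree, item) {
  out <- list(nested_node(list(tree, item), length = 0))  # above the root
  recurse <- function(x, path) {
    res <- list()
    if (is_nested_tip(x)) return(res)
    for (i in seq_along(x$children)) {
      child <- x$children[[i]]
      replaced <- x
      replaced$children[[i]] <- nested_node(list(child, item), length = 0)
      res[[length(res) + 1L]] <- replaced
      for (deeper in recurse(child, path)) {
        rep2 <- x
        rep2$children[[i]] <- deeper
        res[[length(res) + 1L]] <- rep2
      }
    }
    res
  }
  c(out, recurse(tree, NULL))
}

#' Resolve polytomies by exhaustive minimum-cost search
#'
#' Each multifurcation (typically produced by [collapse_weak_edges()]) is
#' replaced by the binary arrangement of its child subtrees that minimizes
#' the total DTL reconciliation cost, searching all (2d-3)!! arrangements of
#' a degree-d polytomy. Polytomies are resolved one at a time in postorder;
#' new internal edges get length 0 and no support. Deterministic tie-break:
#' smallest canonical topology string.
#'
#' @param gene a rooted (possibly non-binary) gene tree.
#' @param species rooted binary species tree.
#' @param costs a [cost_scheme()].
#' @param max_degree largest polytomy degree searched exhaustively
#'   (default 8); larger polytomies raise an error.
#' @return a binary `gene_tree`.
#' @export
resolve_polytomies <- function(gene, species, costs = cost_scheme(),
                               max_degree = 8L) {
  nested <- canonicalize_nested(phylo_to_nested(gene))
  repeat {
    poly <- find_polytomy(nested)
    if (is.null(poly)) break
    if (poly$degree > max_degree)
      stop2("polytomy of degree ", poly$degree, " exceeds max_degree = ",
            max_degree, "; raise the cap or pre-resolve the tree")
    target <- get_at_path(nested, poly$path)
    cands <- binary_arrangements(target$children)
    best <- NULL
    for (cand in cands) {
      cand$length <- target$length
      cand$support <- target$support
      trial <- set_at_path(nested, poly$path, cand)
      phy <- restore_gene_tree(nested_to_phylo(trial), gene)
      res <- reconcile_cost(phy, species, costs)
      key <- nested_to_newick(strip_lengths(canonicalize_nested(trial)))
      if (is.null(best) || res$cost < best$cost - 1e-9 ||
          (abs(res$cost - best$cost) <= 1e-9 && key < best$key)) {
        best <- list(cost = res$cost, key = key, nested = trial)
      }
    }
    nested <- canonicalize_nested(best$nested)
  }
  restore_gene_tree(nested_to_phylo(nested), gene)
}

# first polytomy in postorder; path is the child-index route from the root
find_polytomy <- function(x, path = integer(0)) {
  if (is_nested_tip(x)) return(NULL)
  for (i in seq_along(x$children)) {
    hit <- find_polytomy(x$children[[i]], c(path, i))
    if (!is.null(hit)) return(hit)
  }
  if (length(x$children) > 2L)
    return(list(path = path, degree = length(x$children)))
  NULL
}

get_at_path <- function(x, path) {
  for (i in path) x <- x$children[[i]]
  x
}

set_at_path <- function(x, path, value) {
  if (!length(path)) return(value)
  x$children[[path[1L]]] <-
    set_at_path(x$children[[path[1L]]], path[-1L], value)
  x
}
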