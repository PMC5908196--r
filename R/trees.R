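#' Parse a Newick string into a validated species or gene tree
#'
#' Trees are stored as [ape::read.tree()] `phylo` objects with an extra class
#' (`"species_tree"` or `"gene_tree"`). Numeric internal node labels are
#' interpreted as edge supports and must lie in `[0, 1]`. For gene trees each
#' tip carries a gene id (the tip label) and a species id; by default the
#' species id is the part of the label before the first `"@"` (so a
#' single-copy tree can simply use species names as tip labels), or an
#' explicit mapping can be supplied.
#'
#' @param text a Newick string (must end in `;`).
#' @param kind `"species"` or `"gene"`.
#' @param species_map optional named character vector mapping gene tip labels
#'   to species ids (gene trees only).
#' @return an object of class `c("species_tree", "phylo")` or
#'   `c("gene_tree", "phylo")`. Gene trees carry attributes `species` (named
#'   character vector, tip label -> species id) and `unrooted` (logical).
#' @export
#' @examples
#' sp <- parse_newick("((A:1,B:1):1,C:2);", "species")
#' gt <- parse_newick("((A@1:1,B@1:1)0.95:1,C@1:2);", "gene")
parse_newick <- function(text, kind = c("species", "gene"),
                         species_map = NULL) {
  kind <- match.arg(kind)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop2("malformed Newick string (unparseable): ", substr(text, 1, 60))
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop2("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (kind == "species") {
    if (!ape::is.rooted(phy))
      stop2("species tree must be rooted (binary root)")
    if (!ape::is.binary(phy))
      stop2("species tree must be fully binary")
    class(phy) <- c("species_tree", "phylo")
    return(phy)
  }
  sup <- numeric_node_labels(phy)
  bad <- which(!is.na(sup) & (sup < 0 | sup > 1))
  if (length(bad))
    stop2("edge supports must lie in [0, 1]; offending values: ",
          paste(sup[bad], collapse = ", "))
  sp <- if (!is.null(species_map)) {
    missing <- setdiff(phy$tip.label, names(species_map))
    if (length(missing))
      stop2("species_map lacks entries for: ", paste(missing, collapse = ", "))
    species_map[phy$tip.label]
  } else sub("@.*$", "", phy$tip.label)
  names(sp) <- phy$tip.label
  attr(phy, "species") <- sp
  attr(phy, "unrooted") <- !ape::is.rooted(phy)
  class(phy) <- c("gene_tree", "phylo")
  phy
}

# cheap syntactic pre-check so errors can report a character offset
check_newick_syntax <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop2("expected a single Newick string")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop2("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop2("malformed Newick: ", depth, " unclosed '(' at character ",
          length(chars))
  if (!grepl(";\\s*$", text))
    stop2("malformed Newick: missing terminal ';' at character ",
          length(chars))
  invisible(TRUE)
}

numeric_node_labels <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}

gene_species <- function(tree) {
  sp <- attr(tree, "species")
  if (is.null(sp)) {
    sp <- sub("@.*$", "", tree$tip.label)
    names(sp) <- tree$tip.label
  }
  sp
}

# reinstall gene-tree class/attributes after surgery on the plain phylo
restore_gene_tree <- function(phy, template) {
  sp <- gene_species(template)
  attr(phy, "species") <- sp[phy$tip.label]
  attr(phy, "unrooted") <- FALSE
  class(phy) <- c("gene_tree", "phylo")
  phy
}

#' Write a tree as a canonical Newick string
#'
#' Output is deterministic: at every node children are ordered by their
#' smallest descendant leaf label, supports are emitted as internal node
#' labels and branch lengths are preserved. Two structurally equal trees
#' therefore serialize to byte-identical strings.
#'
#' @param tree a `species_tree`, `gene_tree` or plain `phylo`.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  nested_to_newick(canonicalize_nested(phylo_to_nested(tree)))
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions (unrooted splits of the leaf set)
#' present in exactly one of the two trees. Both trees are treated as
#' unrooted; they must share the same leaf label set.
#'
#' @param t1,t2 trees over the same leaf set.
#' @return a non-negative integer; 0 iff the unrooted topologies agree.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop2("trees have different leaf sets; symmetric difference: ",
          paste(d, collapse = ", "))
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Root a gene tree at the midpoint of its longest leaf-to-leaf path
#'
#' The root is placed halfway along the tree diameter. When several
#' leaf pairs tie for the diameter, the lexicographically smallest ordered
#' leaf pair is used.
#'
#' @param tree a gene tree (or any `phylo`) with branch lengths.
#' @param unit_lengths if `TRUE`, ignore stored branch lengths and treat
#'   every edge as length 1 (fallback for support-only trees).
#' @return the rooted tree (class preserved for gene trees).
#' @export
midpoint_root <- function(tree, unit_lengths = FALSE) {
  idx <- tree_index(tree)
  elen <- idx$elen
  if (unit_lengths) elen[] <- 1
  if (any(is.na(elen[-idx$root])))
    stop2("midpoint rooting needs branch lengths on all edges; ",
          "use unit_lengths = TRUE for a unit-length fallback")
  N <- idx$n_node
  nbr <- vector("list", N)
  for (v in seq_len(N)) nbr[[v]] <- list()
  add_edge <- function(a, b, len, sup) {
    nbr[[a]][[length(nbr[[a]]) + 1L]] <<- list(to = b, len = len, sup = sup)
    nbr[[b]][[length(nbr[[b]]) + 1L]] <<- list(to = a, len = len, sup = sup)
  }
  for (v in seq_len(N)) if (idx$parent[v] > 0L)
    add_edge(idx$parent[v], v, elen[v], idx$support[v])

  dist_from <- function(a) {
    d <- rep(NA_real_, N)
    prev <- integer(N)
    d[a] <- 0
    queue <- a
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in nbr[[v]]) if (is.na(d[e$to])) {
        d[e$to] <- d[v] + e$len
        prev[e$to] <- v
        queue <- c(queue, e$to)
      }
    }
    list(d = d, prev = prev)
  }
  tips <- seq_len(idx$n_tip)
  best <- NULL
  for (a in tips) {
    da <- dist_from(a)
    for (b in tips) {
      if (idx$tip_label[a] >= idx$tip_label[b]) next
      key <- c(idx$tip_label[a], idx$tip_label[b])
      if (is.null(best) || da$d[b] > best$dist + 1e-12 ||
          (abs(da$d[b] - best$dist) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        # reconstruct path a -> b
        path <- b
        while (path[1L] != a) path <- c(da$prev[path[1L]], path)
        best <- list(dist = da$d[b], key = key, path = path, d = da$d)
      }
    }
  }
  half <- best$dist / 2
  # walk along the path from the first leaf of the pair
  acc <- 0
  path <- best$path
  u <- path[1L]
  for (k in seq_len(length(path) - 1L)) {
    v <- path[k + 1L]
    e <- Find(function(e) e$to == v, nbr[[path[k]]])
    if (acc + e$len >= half - 1e-12) {
      u <- path[k]
      pos_u <- half - acc
      edge_sup <- e$sup
      break
    }
    acc <- acc + e$len
  }
  v <- path[which(path == u) + 1L]
  orient <- function(node, from) {
    kids <- Filter(function(e) e$to != from, nbr[[node]])
    if (!length(kids)) {
      out <- nested_tip(idx$tip_label[node])
      return(out)
    }
    nested_node(lapply(kids, function(e) {
      child <- orient(e$to, node)
      child$length <- e$len
      if (!is_nested_tip(child)) child$support <- e$sup
      child
    }))
  }
  eps <- 1e-12
  e_uv <- Find(function(e) e$to == v, nbr[[u]])
  if (pos_u <= eps) {
    rooted <- orient(u, 0L)
  } else if (e_uv$len - pos_u <= eps) {
    rooted <- orient(v, 0L)
  } else {
    left <- orient(u, v); left$length <- pos_u
    if (!is_nested_tip(left)) left$support <- edge_sup
    right <- orient(v, u); right$length <- e_uv$len - pos_u
    if (!is_nested_tip(right)) right$support <- edge_sup
    rooted <- nested_node(list(left, right))
  }
  rooted <- suppress_unary(rooted)
  out <- nested_to_phylo(canonicalize_nested(rooted))
  if (inherits(tree, "gene_tree")) out <- restore_gene_tree(out, tree)
  out
}

# merge single-child internal nodes (appear when the old degree-2 root
# lies inside one of the re-oriented subtrees)
suppress_unary <- function(x) {
  if (is_nested_tip(x)) return(x)
  x$children <- lapply(x$children, suppress_unary)
  x$children <- lapply(x$children, function(ch) {
    while (!is_nested_tip(ch) && length(ch$children) == 1L) {
      g <- ch$children[[1L]]
      g$length <- sum(c(g$length, ch$length), na.rm = TRUE)
      if (!is_nested_tip(g) && is.na(g$support)) g$support <- ch$support
      ch <- g
    }
    ch
  })
  x
}

#' Collapse weakly supported internal edges into polytomies
#'
#' Every internal edge whose support is strictly below `threshold` is
#' contracted; its child's subtrees are attached to the grandparent and the
#' contracted edge's length is added to them, preserving leaf depths. Edges
#' without a support value are treated as fully supported and kept.
#'
#' @param tree a gene tree.
#' @param threshold support threshold in `[0, 1]`; default 0.9 (strict `<`,
#'   so an edge supported at exactly 0.9 survives).
#' @return the (possibly non-binary) collapsed tree.
#' @export
collapse_weak_edges <- function(tree, threshold = 0.9) {
  assert_fraction(threshold, "threshold")
  collapse <- function(x) {
    if (is_nested_tip(x)) return(x)
    x$children <- lapply(x$children, collapse)
    out <- list()
    for (ch in x$children) {
      if (!is_nested_tip(ch) && !is.na(ch$support) && ch$support < threshold) {
        for (g in ch$children) {
          if (!is.na(ch$length)) g$length <- sum(c(g$length, ch$length),
                                                 na.rm = TRUE)
          out[[length(out) + 1L]] <- g
        }
      } else out[[length(out) + 1L]] <- ch
    }
    x$children <- out
    x
  }
  nested <- collapse(phylo_to_nested(tree))
  out <- nested_to_phylo(canonicalize_nested(nested))
  if (inherits(tree, "gene_tree")) out <- restore_gene_tree(out, tree)
  else class(out) <- class(tree)
  out
}
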