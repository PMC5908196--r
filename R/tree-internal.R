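# Internal tree machinery shared by the I/O, reconciliation and SPR code.
#
# Two working representations are used alongside ape's "phylo":
#  * an index (flat arrays keyed by ape node ids) for the dynamic programs;
#  * a nested list (one R list per node) for tree surgery and canonical
#    Newick output, where child order can be normalized cheaply.

n_tips <- function(phy) length(phy$tip.label)

root_node <- function(phy) n_tips(phy) + 1L

# Flat index of a phylo object. Node ids follow ape's convention:
# tips 1..n, root n+1, further internal nodes n+2..n+Nnode.
tree_index <- function(phy) {
  n <- n_tips(phy)
  N <- n + phy$Nnode
  parent <- integer(N)
  elen <- rep(NA_real_, N)
  has_len <- !is.null(phy$edge.length)
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2L]] <- phy$edge[i, 1L]
    if (has_len) elen[phy$edge[i, 2L]] <- phy$edge.length[i]
  }
  children <- vector("list", N)
  for (v in seq_len(N)) children[[v]] <- integer(0)
  for (v in seq_len(N)) if (parent[v] > 0L) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  # postorder: children before parents
  post <- integer(0)
  stack <- root_node(phy)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(seen)
  support <- rep(NA_real_, N)
  if (!is.null(phy$node.label)) {
    lab <- suppressWarnings(as.numeric(phy$node.label))
    support[n + seq_len(phy$Nnode)] <- lab
  }
  clade <- vector("list", N)
  for (v in post) {
    clade[[v]] <- if (v <= n) phy$tip.label[v] else
      sort(unlist(lapply(children[[v]], function(w) clade[[w]])))
  }
  list(n_tip = n, n_node = N, parent = parent, children = children,
       postorder = post, elen = elen, support = support,
       tip_label = phy$tip.label, clade = clade, root = root_node(phy))
}

# deterministic human-readable name for a species/gene node
node_name <- function(idx, v) {
  tips <- idx$clade[[v]]
  if (length(tips) == 1L) tips else
    paste0("mrca(", paste(tips, collapse = ","), ")")
}

num_fmt <- function(x) {
  out <- formatC(x, format = "g", digits = 12)
  gsub(" ", "", out)
}

# ---- nested representation -------------------------------------------------

nested_tip <- function(label, length = NA_real_) {
  list(label = label, length = length, support = NA_real_, children = list())
}

nested_node <- function(children, length = NA_real_, support = NA_real_,
                        label = NA_character_) {
  list(label = label, length = length, support = support, children = children)
}

is_nested_tip <- function(x) length(x$children) == 0L

phylo_to_nested <- function(phy) {
  idx <- tree_index(phy)
  build <- function(v) {
    if (v <= idx$n_tip) return(nested_tip(idx$tip_label[v], idx$elen[v]))
    lab <- NA_character_
    if (!is.null(phy$node.label)) {
      raw <- phy$node.label[v - idx$n_tip]
      if (!is.null(raw) && !is.na(raw) && nzchar(raw) &&
          is.na(suppressWarnings(as.numeric(raw)))) lab <- raw
    }
    nested_node(lapply(idx$children[[v]], build), idx$elen[v],
                idx$support[v], lab)
  }
  build(idx$root)
}

nested_min_tip <- function(x) {
  if (is_nested_tip(x)) return(x$label)
  min(vapply(x$children, nested_min_tip, character(1)))
}

# sort children at every level by smallest descendant tip label
canonicalize_nested <- function(x) {
  if (is_nested_tip(x)) return(x)
  x$children <- lapply(x$children, canonicalize_nested)
  keys <- vapply(x$children, nested_min_tip, character(1))
  x$children <- x$children[order(keys)]
  x
}

nested_to_newick <- function(x, top = TRUE) {
  if (is_nested_tip(x)) {
    s <- x$label
    if (!is.na(x$length)) s <- paste0(s, ":", num_fmt(x$length))
    return(if (top) paste0(s, ";") else s)
  }
  inner <- paste(vapply(x$children, nested_to_newick, character(1),
                        top = FALSE), collapse = ",")
  lab <- if (!is.na(x$support)) num_fmt(x$support)
         else if (!is.na(x$label)) x$label else ""
  s <- paste0("(", inner, ")", lab)
  if (!top && !is.na(x$length)) s <- paste0(s, ":", num_fmt(x$length))
  if (top) paste0(s, ";") else s
}

nested_to_phylo <- function(x) {
  txt <- nested_to_newick(x)
  ape::read.tree(text = txt)
}

nested_tip_labels <- function(x) {
  if (is_nested_tip(x)) return(x$label)
  unlist(lapply(x$children, nested_tip_labels))
}

strip_lengths_phylo <- function(phy) {
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

# ---- unrooted splits -------------------------------------------------------

# canonical key of a bipartition: serialize the lexicographically smaller block
split_key <- function(block, all_tips) {
  other <- setdiff(all_tips, block)
  a <- paste(sort(block), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  if (length(block) < length(other)) return(a)
  if (length(other) < length(block)) return(b)
  if (a < b) a else b
}

# non-trivial unrooted splits of a (rooted or unrooted) tree
tree_splits <- function(phy) {
  idx <- tree_index(phy)
  all_tips <- sort(idx$tip_label)
  keys <- character(0)
  for (v in idx$postorder) {
    if (v <= idx$n_tip || v == idx$root) next
    block <- idx$clade[[v]]
    if (length(block) <= 1L || length(block) >= length(all_tips) - 1L) next
    keys <- c(keys, split_key(block, all_tips))
  }
  unique(keys)
}
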