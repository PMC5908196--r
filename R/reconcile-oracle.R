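# Exhaustive-enumeration oracle for the DTL optimum. Independent of the
# dynamic program: every assignment of internal gene nodes to species
# locations is enumerated, the implied event at each node is classified from
# the (node, child, child) location triple, and the minimal implied losses
# are added. Shares only the model conventions with dtl_reconcile (undated
# transfers between incomparable edges; family present at the species root).

#' Exact minimum DTL cost by exhaustive enumeration (test oracle)
#'
#' Enumerates all assignments of internal gene-tree nodes to species-tree
#' locations and replays the implied events, returning the exact minimum
#' cost. Exponential in the gene-tree size; restricted to trees with at most
#' 7 leaves each. Used to certify [dtl_reconcile()] on small instances.
#'
#' @inheritParams dtl_reconcile
#' @return the minimal total cost (a number).
#' @export
bruteforce_min_cost <- function(gene, species, costs = cost_scheme()) {
  if (n_tips(gene) > 7L || n_tips(species) > 7L)
    stop2("bruteforce oracle limited to <= 7 leaves per tree")
  gidx <- tree_index(gene)
  sidx <- species_index(species)
  gmap <- map_gene_tips(gene, sidx)
  Ns <- sidx$n_node
  depth <- sidx$depth
  anc <- sidx$anc
  incomp <- sidx$incomp
  lc <- costs$loss

  # H[s, s2]: minimal losses to deliver a transferred lineage (donor s)
  # down to s2: enter at the deepest ancestor-or-self of s2 that is
  # incomparable to s (usually s2 itself), then descend. Inf when no
  # incomparable entry point exists.
  H <- matrix(Inf, Ns, Ns)
  for (s2 in seq_len(Ns)) {
    chain <- s2
    v <- s2
    while (sidx$parent[v] > 0L) { v <- sidx$parent[v]; chain <- c(chain, v) }
    for (s in seq_len(Ns)) {
      ok <- chain[incomp[s, chain]]
      if (length(ok)) H[s, s2] <- (depth[s2] - max(depth[ok])) * lc
    }
  }

  tcost <- costs$transfer
  A <- array(Inf, dim = c(Ns, Ns, Ns))  # event cost at s, children at s1,s2
  for (s in seq_len(Ns)) {
    sk <- sidx$children[[s]]
    for (s1 in seq_len(Ns)) for (s2 in seq_len(Ns)) {
      best <- Inf
      if (length(sk) == 2L) {
        l <- sk[1L]; r <- sk[2L]
        if (anc[l, s1] && anc[r, s2])
          best <- min(best, lc * (depth[s1] - depth[l] + depth[s2] - depth[r]))
        if (anc[r, s1] && anc[l, s2])
          best <- min(best, lc * (depth[s1] - depth[r] + depth[s2] - depth[l]))
      }
      if (anc[s, s1] && anc[s, s2])
        best <- min(best, costs$dup +
                      lc * (depth[s1] + depth[s2] - 2 * depth[s]))
      if (is.finite(tcost)) {
        if (anc[s, s1] && is.finite(H[s, s2]))
          best <- min(best, tcost + lc * (depth[s1] - depth[s]) + H[s, s2])
        if (anc[s, s2] && is.finite(H[s, s1]))
          best <- min(best, tcost + lc * (depth[s2] - depth[s]) + H[s, s1])
      }
      A[s, s1, s2] <- best
    }
  }

  internal <- gidx$postorder[gidx$postorder > gidx$n_tip]
  k <- length(internal)
  slot <- stats::setNames(seq_len(k), internal)
  tip_loc <- function(g) unname(gmap[gidx$tip_label[g]])

  # vectorized enumeration over the Ns^k assignment grid, chunked on the
  # last internal node to bound memory on 7-leaf instances
  grid_col <- function(j, k_eff, n_rows) {
    rep(rep(seq_len(Ns), each = Ns^(j - 1L)), length.out = n_rows)
  }
  eval_chunk <- function(fixed_last) {
    k_eff <- if (is.null(fixed_last)) k else k - 1L
    n_rows <- Ns^k_eff
    cols <- lapply(seq_len(k_eff), grid_col, k_eff = k_eff, n_rows = n_rows)
    if (!is.null(fixed_last)) cols[[k]] <- rep.int(fixed_last, n_rows)
    total <- numeric(n_rows)
    for (g in internal) {
      kids <- gidx$children[[g]]
      m_g <- cols[[slot[[as.character(g)]]]]
      m1 <- if (kids[1L] <= gidx$n_tip) rep.int(tip_loc(kids[1L]), n_rows)
            else cols[[slot[[as.character(kids[1L])]]]]
      m2 <- if (kids[2L] <= gidx$n_tip) rep.int(tip_loc(kids[2L]), n_rows)
            else cols[[slot[[as.character(kids[2L])]]]]
      total <- total + A[cbind(m_g, m1, m2)]
    }
    root_col <- cols[[slot[[as.character(gidx$root)]]]]
    total <- total + lc * depth[root_col]  # stem losses: family enters at root
    min(total)
  }
  if (Ns^k <= 2e6) return(eval_chunk(NULL))
  min(vapply(seq_len(Ns), eval_chunk, numeric(1)))
}
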