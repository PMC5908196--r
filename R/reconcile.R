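#' Event cost scheme for duplication-transfer-loss reconciliation
#'
#' Speciation is free; duplication, transfer and loss carry positive costs.
#' The defaults (dup = 1, transfer = 2, loss = 1) encode a transfer twice as
#' expensive as a duplication, the primary transfer:duplication ratio used by
#' the family classifier; ratios 4 and 6 are obtained by raising `transfer`.
#'
#' @param dup,transfer,loss positive event costs (`transfer` may be `Inf`
#'   to forbid transfers).
#' @return an object of class `cost_scheme`.
#' @export
cost_scheme <- function(dup = 1, transfer = 2, loss = 1) {
  if (!is_scalar_number(dup) || dup <= 0) stop2("dup cost must be > 0")
  if (!is_scalar_number(loss) || loss <= 0) stop2("loss cost must be > 0")
  if (!(is.numeric(transfer) && length(transfer) == 1L &&
        (is.infinite(transfer) || transfer > 0)))
    stop2("transfer cost must be > 0 (or Inf)")
  structure(list(dup = dup, transfer = transfer, loss = loss,
                 ratio = transfer / dup),
            class = "cost_scheme")
}

# ---- species-side index ----------------------------------------------------

species_index <- function(species) {
  idx <- tree_index(species)
  N <- idx$n_node
  anc <- matrix(FALSE, N, N)  # anc[i, j]: i is ancestor-of-or-equal-to j
  for (v in idx$postorder) {
    anc[v, v] <- TRUE
    for (w in idx$children[[v]]) anc[v, ] <- anc[v, ] | anc[w, ]
  }
  depth <- integer(N)  # edges from root
  for (v in rev(idx$postorder)) if (idx$parent[v] > 0L)
    depth[v] <- depth[idx$parent[v]] + 1L
  incomp <- !(anc | t(anc))
  idx$anc <- anc
  idx$depth <- depth
  idx$incomp <- incomp
  idx$tip_id <- stats::setNames(seq_len(idx$n_tip), idx$tip_label)
  idx
}

map_gene_tips <- function(gene, sidx) {
  sp <- gene_species(gene)
  missing <- setdiff(unique(sp), names(sidx$tip_id))
  if (length(missing))
    stop2("gene-tree species not in species tree: ",
          paste(missing, collapse = ", "))
  stats::setNames(sidx$tip_id[sp], names(sp))
}

# ---- the undated DTL dynamic program ---------------------------------------
#
# States per gene node g and species node s ("s" denotes the edge above s;
# the species root stands for the root edge):
#   C[g,s]  - optimal cost with g's event located at s
#   IN[g,s] - optimal cost with g's lineage entering at the top of edge s
#             (may descend, one loss per bypassed sibling edge)
#   OUT[g,s]- optimal cost of placing g anywhere incomparable to s
# Pairs (cost, transfer count) are minimized lexicographically so that the
# returned co-optimum has the fewest transfers. The family is assumed present
# at the species root: the answer is IN[gene root, species root], which
# charges losses between the species root and the root's mapping.

lex_lt <- function(c1, t1, c2, t2, eps = 1e-9) {
  if (!is.finite(c1)) return(FALSE)      # an unreachable candidate never wins
  if (!is.finite(c2)) return(TRUE)
  c1 < c2 - eps || (abs(c1 - c2) <= eps && t1 < t2)
}

lex_eq <- function(c1, t1, c2, t2, eps = 1e-9) {
  if (!is.finite(c1) || !is.finite(c2)) return(FALSE)
  abs(c1 - c2) <= eps && t1 == t2
}

dtl_tables <- function(gidx, sidx, gmap, costs, allow_transfer = TRUE) {
  Ng <- gidx$n_node
  Ns <- sidx$n_node
  INF <- Inf
  C <- matrix(INF, Ng, Ns); Tc <- matrix(0L, Ng, Ns)
  IN <- matrix(INF, Ng, Ns); Tin <- matrix(0L, Ng, Ns)
  OUT <- matrix(INF, Ng, Ns); Tout <- matrix(0L, Ng, Ns)
  allow_transfer <- allow_transfer && is.finite(costs$transfer)
  spost <- sidx$postorder
  for (g in gidx$postorder) {
    if (g <= gidx$n_tip) {
      C[g, gmap[gidx$tip_label[g]]] <- 0
    } else {
      kids <- gidx$children[[g]]
      if (length(kids) != 2L)
        stop2("gene tree must be binary for reconciliation; ",
              "resolve polytomies first (see resolve_polytomies)")
      g1 <- kids[1L]; g2 <- kids[2L]
      for (s in spost) {
        bc <- INF; bt <- 0L
        take <- function(cost, tr) {
          if (lex_lt(cost, tr, bc, bt)) { bc <<- cost; bt <<- tr }
        }
        sk <- sidx$children[[s]]
        if (length(sk) == 2L) {
          l <- sk[1L]; r <- sk[2L]
          take(IN[g1, l] + IN[g2, r], Tin[g1, l] + Tin[g2, r])
          take(IN[g1, r] + IN[g2, l], Tin[g1, r] + Tin[g2, l])
        }
        take(costs$dup + IN[g1, s] + IN[g2, s], Tin[g1, s] + Tin[g2, s])
        if (allow_transfer) {
          take(costs$transfer + IN[g1, s] + OUT[g2, s],
               1L + Tin[g1, s] + Tout[g2, s])
          take(costs$transfer + IN[g2, s] + OUT[g1, s],
               1L + Tin[g2, s] + Tout[g1, s])
        }
        C[g, s] <- bc; Tc[g, s] <- bt
      }
    }
    for (s in spost) {
      bc <- C[g, s]; bt <- Tc[g, s]
      for (cs in sidx$children[[s]]) {
        cand <- IN[g, cs] + costs$loss
        if (lex_lt(cand, Tin[g, cs], bc, bt)) { bc <- cand; bt <- Tin[g, cs] }
      }
      IN[g, s] <- bc; Tin[g, s] <- bt
    }
    if (allow_transfer) {
      for (s in seq_len(Ns)) {
        bc <- INF; bt <- 0L
        for (s2 in which(sidx$incomp[s, ])) {
          if (lex_lt(IN[g, s2], Tin[g, s2], bc, bt)) {
            bc <- IN[g, s2]; bt <- Tin[g, s2]
          }
        }
        OUT[g, s] <- bc; Tout[g, s] <- bt
      }
    }
  }
  list(C = C, Tc = Tc, IN = IN, Tin = Tin, OUT = OUT, Tout = Tout,
       allow_transfer = allow_transfer)
}

# Backtrack the canonical co-optimal solution: (cost, transfers)
# lexicographic, then event priority speciation > duplication > transfer,
# first child / first species child preferred.
dtl_backtrack <- function(tb, gidx, sidx, gmap, costs) {
  events <- list()
  mapping <- character(gidx$n_node)
  emit <- function(kind, g, s, donor = NA_integer_, recipient = NA_integer_) {
    events[[length(events) + 1L]] <<- list(
      kind = kind,
      gene_node = if (is.na(g)) NA_character_ else gene_node_name(gidx, g),
      location = node_name(sidx, s),
      donor = if (is.na(donor)) NA_character_ else node_name(sidx, donor),
      recipient = if (is.na(recipient)) NA_character_ else
        node_name(sidx, recipient))
  }
  bt_in <- function(g, s) {
    repeat {
      if (lex_eq(tb$IN[g, s], tb$Tin[g, s], tb$C[g, s], tb$Tc[g, s])) break
      moved <- FALSE
      for (cs in sidx$children[[s]]) {
        if (lex_eq(tb$IN[g, s], tb$Tin[g, s],
                   tb$IN[g, cs] + costs$loss, tb$Tin[g, cs])) {
          sib <- setdiff(sidx$children[[s]], cs)
          emit("loss", NA_integer_, sib)
          s <- cs
          moved <- TRUE
          break
        }
      }
      if (!moved) stop2("internal error: inconsistent DTL backtrack (in)")
    }
    bt_c(g, s)
  }
  bt_c <- function(g, s) {
    mapping[g] <<- node_name(sidx, s)
    if (g <= gidx$n_tip) return(invisible())
    kids <- gidx$children[[g]]
    g1 <- kids[1L]; g2 <- kids[2L]
    cc <- tb$C[g, s]; ct <- tb$Tc[g, s]
    sk <- sidx$children[[s]]
    if (length(sk) == 2L) {
      for (ori in list(c(1L, 2L), c(2L, 1L))) {
        a <- kids[ori[1L]]; b <- kids[ori[2L]]
        if (lex_eq(cc, ct, tb$IN[a, sk[1L]] + tb$IN[b, sk[2L]],
                   tb$Tin[a, sk[1L]] + tb$Tin[b, sk[2L]])) {
          emit("speciation", g, s)
          bt_in(a, sk[1L]); bt_in(b, sk[2L])
          return(invisible())
        }
      }
    }
    if (lex_eq(cc, ct, costs$dup + tb$IN[g1, s] + tb$IN[g2, s],
               tb$Tin[g1, s] + tb$Tin[g2, s])) {
      emit("duplication", g, s)
      bt_in(g1, s); bt_in(g2, s)
      return(invisible())
    }
    if (tb$allow_transfer) {
      for (ori in list(c(g1, g2), c(g2, g1))) {
        stay <- ori[1L]; move <- ori[2L]
        if (lex_eq(cc, ct,
                   costs$transfer + tb$IN[stay, s] + tb$OUT[move, s],
                   1L + tb$Tin[stay, s] + tb$Tout[move, s])) {
          rec <- NA_integer_
          for (s2 in which(sidx$incomp[s, ])) {
            if (lex_eq(tb$OUT[move, s], tb$Tout[move, s],
                       tb$IN[move, s2], tb$Tin[move, s2])) { rec <- s2; break }
          }
          emit("transfer", g, s, donor = s, recipient = rec)
          bt_in(stay, s); bt_in(move, rec)
          return(invisible())
        }
      }
    }
    stop2("internal error: inconsistent DTL backtrack (event)")
  }
  root_s <- sidx$root
  g_root <- gidx$root
  bt_in(g_root, root_s)
  ev <- do.call(rbind, lapply(events, function(e)
    data.frame(kind = e$kind, gene_node = e$gene_node, location = e$location,
               donor = e$donor, recipient = e$recipient,
               stringsAsFactors = FALSE)))
  if (is.null(ev))
    ev <- data.frame(kind = character(0), gene_node = character(0),
                     location = character(0), donor = character(0),
                     recipient = character(0), stringsAsFactors = FALSE)
  gene_names <- vapply(seq_len(gidx$n_node), function(g)
    gene_node_name(gidx, g), character(1))
  list(events = ev, mapping = stats::setNames(mapping, gene_names))
}

gene_node_name <- function(gidx, g) {
  if (g <= gidx$n_tip) return(gidx$tip_label[g])
  node_name(gidx, g)
}

new_reconciliation <- function(cost, events, mapping, costs, mode) {
  nD <- sum(events$kind == "duplication")
  nT <- sum(events$kind == "transfer")
  nL <- sum(events$kind == "loss")
  structure(list(cost = cost, n_duplication = nD, n_transfer = nT,
                 n_loss = nL, events = events, mapping = mapping,
                 costs = costs, mode = mode),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("%s reconciliation: cost %.6g (%d duplication, %d transfer, %d loss)\n",
              toupper(x$mode), x$cost, x$n_duplication, x$n_transfer,
              x$n_loss))
  tr <- x$events[x$events$kind == "transfer", , drop = FALSE]
  if (nrow(tr))
    for (i in seq_len(nrow(tr)))
      cat(sprintf("  transfer at %s: donor %s -> recipient %s\n",
                  tr$gene_node[i], tr$donor[i], tr$recipient[i]))
  invisible(x)
}

reconcile_impl <- function(gene, species, costs, allow_transfer) {
  if (!inherits(species, "phylo")) stop2("species must be a species_tree")
  if (isTRUE(attr(gene, "unrooted")))
    stop2("gene tree is unrooted; root it first (see optimal_root)")
  gidx <- tree_index(gene)
  sidx <- species_index(species)
  gmap <- map_gene_tips(gene, sidx)
  tb <- dtl_tables(gidx, sidx, gmap, costs, allow_transfer)
  total <- tb$IN[gidx$root, sidx$root]
  n_tr <- tb$Tin[gidx$root, sidx$root]
  bt <- dtl_backtrack(tb, gidx, sidx, gmap, costs)
  rec <- new_reconciliation(total, bt$events, bt$mapping, costs,
                            if (allow_transfer && is.finite(costs$transfer))
                              "dtl" else "dl")
  # internal consistency: cost identity must hold by construction
  implied <- rec$n_duplication * costs$dup + rec$n_loss * costs$loss +
    rec$n_transfer * (if (is.finite(costs$transfer)) costs$transfer else 0)
  if (abs(implied - total) > 1e-6)
    stop2("internal error: event list does not reproduce the optimal cost")
  rec
}

#' Minimum-cost duplication-transfer-loss reconciliation
#'
#' Embeds a rooted binary gene tree into the rooted species tree under the
#' undated DTL model: transfers are allowed between any two species edges
#' neither of which is ancestral to the other. The gene family is assumed
#' ancestrally present at the species root, so losses along the path from the
#' species root to the root's mapping are charged. Among co-optimal
#' solutions, the one with the fewest transfers is returned, with remaining
#' ties broken by a deterministic traversal preferring
#' speciation > duplication > transfer.
#'
#' @param gene rooted binary `gene_tree` (every leaf's species must occur in
#'   `species`).
#' @param species rooted binary `species_tree`.
#' @param costs a [cost_scheme()].
#' @return a `reconciliation`: total cost, event counts, an ordered event
#'   table (kind, gene node, species location, transfer donor/recipient) and
#'   the gene-node to species-location mapping.
#' @export
#' @examples
#' sp <- parse_newick("((A,B),C);", "species")
#' gt <- parse_newick("((A,C),B);", "gene")
#' dtl_reconcile(gt, sp, cost_scheme(1, 2, 1))$cost  # 3
dtl_reconcile <- function(gene, species, costs = cost_scheme()) {
  reconcile_impl(gene, species, costs, allow_transfer = TRUE)
}

#' Duplication-loss reconciliation (transfers forbidden)
#'
#' Identical model to [dtl_reconcile()] with the transfer cost taken as
#' infinite; the result is the classical duplication-loss parsimony of the
#' last-common-ancestor mapping (plus stem losses when the gene leaves do not
#' span the species root). Its cost is always >= the DTL cost.
#'
#' @inheritParams dtl_reconcile
#' @return a `reconciliation` with zero transfers.
#' @export
dl_reconcile <- function(gene, species, costs = cost_scheme()) {
  reconcile_impl(gene, species, costs, allow_transfer = FALSE)
}

#' Check a reconciliation by replaying its event history
#'
#' Walks the gene tree with the reconciliation's node-to-location mapping and
#' verifies, node by node, that the recorded event is legal at its location
#' (speciation children enter distinct species subtrees; transfer donor and
#' recipient are incomparable; duplicated/stay lineages remain below their
#' location), that every implied descent is matched by a recorded loss, and
#' that every gene leaf lands on its own species. Together these imply that
#' replaying the event list regenerates the gene-tree leaf multiset exactly.
#'
#' @param rec a `reconciliation` from [dtl_reconcile()]/[dl_reconcile()].
#' @param gene,species the trees it was computed from.
#' @return `TRUE` (invisibly); errors describe the first violation.
#' @export
check_reconciliation <- function(rec, gene, species) {
  gidx <- tree_index(gene)
  sidx <- species_index(species)
  gmap <- map_gene_tips(gene, sidx)
  sname <- vapply(seq_len(sidx$n_node), function(s) node_name(sidx, s),
                  character(1))
  sid <- stats::setNames(seq_len(sidx$n_node), sname)
  loc <- function(g) sid[[rec$mapping[[gene_node_name(gidx, g)]]]]
  implied_losses <- 0L
  path_losses <- function(top, bottom) {
    if (!sidx$anc[top, bottom]) stop2("replay: mapping escapes its lineage")
    sidx$depth[bottom] - sidx$depth[top]
  }
  for (g in gidx$postorder) {
    s <- loc(g)
    if (g <= gidx$n_tip) {
      if (s != gmap[gidx$tip_label[g]])
        stop2("replay: gene leaf ", gidx$tip_label[g],
              " not mapped to its own species")
      next
    }
    kids <- gidx$children[[g]]
    s1 <- loc(kids[1L]); s2 <- loc(kids[2L])
    ev <- rec$events[rec$events$kind != "loss" &
                       rec$events$gene_node == gene_node_name(gidx, g), ,
                     drop = FALSE]
    if (nrow(ev) != 1L) stop2("replay: no unique event for gene node ",
                              gene_node_name(gidx, g))
    kind <- ev$kind
    if (kind == "speciation") {
      sk <- sidx$children[[s]]
      if (length(sk) != 2L) stop2("replay: speciation at a terminal edge")
      ok1 <- sidx$anc[sk[1L], s1] && sidx$anc[sk[2L], s2]
      ok2 <- sidx$anc[sk[2L], s1] && sidx$anc[sk[1L], s2]
      if (!ok1 && !ok2)
        stop2("replay: speciation children do not enter distinct subtrees")
      if (ok1)
        implied_losses <- implied_losses + path_losses(sk[1L], s1) +
          path_losses(sk[2L], s2)
      else
        implied_losses <- implied_losses + path_losses(sk[2L], s1) +
          path_losses(sk[1L], s2)
    } else if (kind == "duplication") {
      implied_losses <- implied_losses + path_losses(s, s1) +
        path_losses(s, s2)
    } else if (kind == "transfer") {
      rcp <- sid[[ev$recipient]]
      if (!sidx$incomp[s, rcp])
        stop2("replay: transfer donor and recipient are comparable")
      stays <- if (sidx$anc[s, s1]) c(s1, s2) else c(s2, s1)
      if (!sidx$anc[s, stays[1L]])
        stop2("replay: no transfer child remains below the donor")
      if (!sidx$anc[rcp, stays[2L]])
        stop2("replay: transferred child escapes the recipient")
      implied_losses <- implied_losses + path_losses(s, stays[1L]) +
        path_losses(rcp, stays[2L])
    } else stop2("replay: unknown event kind ", kind)
  }
  implied_losses <- implied_losses +
    path_losses(sidx$root, loc(gidx$root))  # stem of the family
  if (implied_losses != rec$n_loss)
    stop2("replay: recorded losses (", rec$n_loss,
          ") do not match implied losses (", implied_losses, ")")
  invisible(TRUE)
}
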