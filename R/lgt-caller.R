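# The end-to-end LGT decision procedure: homolog filtering, the SPR/RF
# cross-check, per-family classification across transfer:duplication cost
# ratios, donor assignment and the aggregate summary.

#' Filter homology hits on coverage and E-value
#'
#' Retains hits with query coverage strictly greater than `min_coverage` and
#' E-value strictly smaller than `max_evalue` (defaults: coverage > 90%,
#' E < 1e-100). Input order is preserved.
#'
#' @param hits data.frame with numeric columns `coverage` (fraction in
#'   `[0, 1]`) and `evalue` (>= 0); other columns pass through.
#' @param min_coverage,max_evalue the cutoffs.
#' @return the retained rows (possibly none).
#' @export
filter_homologs <- function(hits, min_coverage = 0.90, max_evalue = 1e-100) {
  if (!all(c("coverage", "evalue") %in% names(hits)))
    stop2("hits must have columns coverage and evalue")
  if (any(hits$coverage < 0 | hits$coverage > 1, na.rm = TRUE))
    stop2("coverage must lie in [0, 1]")
  if (any(hits$evalue < 0, na.rm = TRUE)) stop2("e-values must be >= 0")
  keep <- hits$coverage > min_coverage & hits$evalue < max_evalue
  hits[which(keep), , drop = FALSE]
}

#' Remove duplicate sequences within species
#'
#' For identical sequences sharing a species id, only the first record (by
#' input order) is kept; identical sequences from different species, and
#' distinct sequences from one species, are all retained.
#'
#' @param records data.frame with columns `species` and `sequence`.
#' @return the de-duplicated rows, input order preserved.
#' @export
dedupe_by_species <- function(records) {
  if (!all(c("species", "sequence") %in% names(records)))
    stop2("records must have columns species and sequence")
  key <- paste(records$species, records$sequence, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

# ---- SPR scan --------------------------------------------------------------

# one tip per species: keep the tip whose root path has the highest minimal
# support (missing supports count as 1.0); ties -> lexicographically
# smallest gene id
prune_to_one_tip_per_species <- function(gene) {
  idx <- tree_index(gene)
  sp <- gene_species(gene)
  path_support <- function(tip) {
    v <- idx$parent[tip]
    m <- 1
    while (v != 0L && v != idx$root) {
      s <- idx$support[v]
      if (!is.na(s)) m <- min(m, s)
      v <- idx$parent[v]
    }
    m
  }
  scores <- vapply(seq_len(idx$n_tip), path_support, numeric(1))
  keep <- character(0)
  for (s in unique(sp)) {
    cand <- which(sp[idx$tip_label] == s)
    best <- cand[order(-scores[cand], idx$tip_label[cand])][1L]
    keep <- c(keep, idx$tip_label[best])
  }
  out <- if (length(keep) < idx$n_tip) ape::keep.tip(gene, keep) else gene
  out$tip.label <- unname(sp[out$tip.label])
  class(out) <- "phylo"
  out
}

# all SPR rearrangements of a rooted nested tree (topology only)
spr_neighbors <- function(nested) {
  paths <- enumerate_paths(nested)
  out <- list()
  for (p in paths) {
    cut <- remove_at_path(nested, p)
    if (is.null(cut)) next
    parent_tips <- nested_tip_labels(get_at_path(nested, p[-length(p)]))
    clade_tips <- sort(nested_tip_labels(cut$pruned))
    src_tips <- sort(setdiff(parent_tips, clade_tips))
    spots <- c(list(integer(0)), enumerate_paths(cut$tree))
    for (q in spots) {
      out[[length(out) + 1L]] <-
        list(tree = insert_at_path(cut$tree, q, cut$pruned),
             clade = clade_tips, src = src_tips,
             dest = sort(nested_tip_labels(get_at_path(cut$tree, q))))
    }
  }
  out
}

enumerate_paths <- function(x, path = integer(0)) {
  if (is_nested_tip(x)) return(list())
  res <- list()
  for (i in seq_along(x$children)) {
    res[[length(res) + 1L]] <- c(path, i)
    res <- c(res, enumerate_paths(x$children[[i]], c(path, i)))
  }
  res
}

remove_at_path <- function(x, path) {
  parent_path <- path[-length(path)]
  parent <- get_at_path(x, parent_path)
  if (length(parent$children) < 2L) return(NULL)
  pruned <- parent$children[[path[length(path)]]]
  parent$children[[path[length(path)]]] <- NULL
  if (length(parent$children) == 1L) parent <- parent$children[[1L]]
  if (!length(parent_path) && is_nested_tip(parent)) return(NULL)
  list(tree = set_at_path(x, parent_path, parent), pruned = pruned)
}

insert_at_path <- function(x, path, subtree) {
  target <- get_at_path(x, path)
  set_at_path(x, path, nested_node(list(target, subtree)))
}

#' Greedy SPR scan for transfer-like discordance
#'
#' Operationalizes the Robinson-Foulds cross-check of inferred transfers:
#' the gene tree is restricted to one tip per species, midpoint-rooted, and
#' greedily rearranged by subtree-prune-and-regraft moves, each chosen to
#' maximally reduce the RF distance to the species tree. Every accepted move
#' is reported as a candidate transfer (moved clade and destination edge).
#' The scan stops at RF distance 0, after `max_moves` moves, or when no
#' single move reduces the distance.
#'
#' @param gene a gene tree (multi-copy allowed; see Details on pruning).
#' @param species rooted binary species tree.
#' @param max_moves maximum number of accepted moves (default 5).
#' @return a list: `moves` (each with the moved `clade`, its former sibling
#'   `src` and the destination `dest`, as species sets), `start_rf`,
#'   `final_rf`, and `resolved` (final distance is 0).
#' @export
spr_transfer_scan <- function(gene, species, max_moves = 5L) {
  pruned <- prune_to_one_tip_per_species(gene)
  if (n_tips(pruned) < 3L) {
    return(list(moves = list(), start_rf = 0L, final_rf = 0L,
                resolved = TRUE))
  }
  has_len <- !is.null(pruned$edge.length) && !anyNA(pruned$edge.length)
  rooted <- midpoint_root(pruned, unit_lengths = !has_len)
  cur <- strip_lengths(canonicalize_nested(phylo_to_nested(rooted)))
  ref <- ape::keep.tip(species, pruned$tip.label)
  # rooted comparison: both trees are rooted (the gene tree by midpoint),
  # so discordance is measured on clade sets, not unrooted splits -
  # a transfer across the species root is visible only in rooted distance
  ref_splits <- nested_clades(canonicalize_nested(phylo_to_nested(ref)))
  rf_to_ref <- function(nested) {
    s <- nested_clades(nested)
    length(setdiff(s, ref_splits)) + length(setdiff(ref_splits, s))
  }
  rf <- rf_to_ref(cur)
  start_rf <- rf
  moves <- list()
  while (rf > 0L && length(moves) < max_moves) {
    best <- NULL
    for (cand in spr_neighbors(cur)) {
      canon <- canonicalize_nested(cand$tree)
      d <- rf_to_ref(canon)
      key <- nested_to_newick(canon)
      if (is.null(best) || d < best$rf || (d == best$rf && key < best$key)) {
        best <- list(rf = d, key = key, tree = canon, clade = cand$clade,
                     src = cand$src, dest = cand$dest)
      }
    }
    if (is.null(best) || best$rf >= rf) break
    moves[[length(moves) + 1L]] <- list(clade = best$clade, src = best$src,
                                        dest = best$dest)
    cur <- best$tree
    rf <- best$rf
  }
  list(moves = moves, start_rf = start_rf, final_rf = rf,
       resolved = rf == 0L)
}

# non-trivial clades (rooted splits) of a nested tree
nested_clades <- function(nested) {
  n_all <- length(nested_tip_labels(nested))
  keys <- character(0)
  walk <- function(x, at_root) {
    if (is_nested_tip(x)) return(invisible())
    if (!at_root) {
      block <- nested_tip_labels(x)
      if (length(block) > 1L && length(block) < n_all)
        keys <<- c(keys, paste(sort(block), collapse = "|"))
    }
    for (ch in x$children) walk(ch, FALSE)
  }
  walk(nested, TRUE)
  unique(keys)
}

# ---- classification --------------------------------------------------------

species_set_of <- function(sidx, name) {
  for (v in seq_len(sidx$n_node))
    if (node_name(sidx, v) == name) return(sidx$clade[[v]])
  stop2("unknown species location: ", name)
}

transfers_into_focal <- function(rec, sidx, focal_clade) {
  tr <- rec$events[rec$events$kind == "transfer", , drop = FALSE]
  if (!nrow(tr)) return(tr)
  into <- vapply(tr$recipient, function(r)
    length(intersect(species_set_of(sidx, r), focal_clade)) > 0L, logical(1))
  tr[into, , drop = FALSE]
}

# transfers whose inferred donor (but not recipient) touches the focal
# clade: parsimony cannot orient a transfer, so these are treated as
# direction-ambiguous acquisitions with the recipient side as the partner
rec_focal_donor <- function(rec, sidx, focal_clade) {
  tr <- rec$events[rec$events$kind == "transfer", , drop = FALSE]
  if (!nrow(tr)) return(tr)
  keep <- vapply(seq_len(nrow(tr)), function(i) {
    don <- species_set_of(sidx, tr$donor[i])
    rcp <- species_set_of(sidx, tr$recipient[i])
    length(intersect(don, focal_clade)) > 0L &&
      length(intersect(rcp, focal_clade)) == 0L
  }, logical(1))
  tr[keep, , drop = FALSE]
}

#' Classify one gene family as vertical, lgt, unresolved or conflicting
#'
#' Runs the per-family decision procedure: weakly supported edges are
#' collapsed at `threshold`, remaining polytomies resolved at minimum cost,
#' and the family reconciled at every transfer:duplication ratio in `ratios`
#' (duplication = loss = 1, transfer = ratio). The category is assigned at
#' the primary (smallest) ratio:
#' * `unresolved` - the family contains only focal-clade sequences;
#' * `vertical`   - zero transfers in the optimal reconciliation;
#' * `lgt`        - transfers inferred, the DTL optimum is strictly cheaper
#'   than the transfers-forbidden (duplication-loss) optimum, and the
#'   independent SPR/RF scan proposes at least one rearrangement involving
#'   the focal clade;
#' * `conflicting` - discordant topology without that support.
#'
#' @param gene a rooted gene tree.
#' @param species rooted binary species tree.
#' @param focal_clade character vector of focal species ids.
#' @param ratios transfer:duplication cost ratios, default `c(2, 4, 6)`;
#'   the smallest is the primary ratio.
#' @param threshold support-collapse threshold, default 0.9.
#' @param taxonomy optional data.frame (`species`, `genus`, `order`,
#'   `class`) for donor naming.
#' @param family id recorded in the result.
#' @param max_moves SPR scan budget.
#' @return an object of class `family_classification`: the category, donor
#'   lineage(s), per-ratio transfer counts and costs, the DL cost, SPR scan
#'   result, a `pre_diversification` flag (transfer onto the branch
#'   ancestral to the whole focal clade) and a `ratio_dependent` instability
#'   flag.
#' @export
classify_family <- function(gene, species, focal_clade,
                            ratios = c(2, 4, 6), threshold = 0.9,
                            taxonomy = NULL, family = NA_character_,
                            max_moves = 5L) {
  if (!length(ratios)) stop2("need at least one cost ratio")
  ratios <- sort(ratios)
  primary <- ratios[1L]
  sp_tips <- unique(unname(gene_species(gene)))
  all_focal <- all(sp_tips %in% focal_clade)
  res <- list(family = family, category = NA_character_,
              donor = character(0), pre_diversification = FALSE,
              ratio_dependent = FALSE, spr = NULL,
              per_ratio = data.frame(ratio = ratios,
                                     transfers = NA_integer_,
                                     dtl_cost = NA_real_,
                                     dl_cost = NA_real_),
              n_tip = n_tips(gene))
  if (all_focal) {
    res$category <- "unresolved"
    return(structure(res, class = "family_classification"))
  }
  if (n_tips(gene) < 2L) {
    res$category <- "vertical"  # single non-focal-only leaf: no discordance
    return(structure(res, class = "family_classification"))
  }
  work <- collapse_weak_edges(gene, threshold)
  work <- resolve_polytomies(work, species, cost_scheme(1, primary, 1))
  sidx <- species_index(species)
  dl <- dl_reconcile(work, species, cost_scheme(1, Inf, 1))
  recs <- list()
  for (i in seq_along(ratios)) {
    rec <- dtl_reconcile(work, species, cost_scheme(1, ratios[i], 1))
    recs[[i]] <- rec
    res$per_ratio$transfers[i] <- rec$n_transfer
    res$per_ratio$dtl_cost[i] <- rec$cost
    res$per_ratio$dl_cost[i] <- dl$cost
  }
  res$ratio_dependent <- length(unique(res$per_ratio$transfers)) > 1L
  primary_rec <- recs[[1L]]
  if (primary_rec$n_transfer == 0L) {
    res$category <- "vertical"
    return(structure(res, class = "family_classification"))
  }
  scan <- spr_transfer_scan(work, species, max_moves = max_moves)
  res$spr <- scan
  focal_move <- any(vapply(scan$moves, function(m)
    length(intersect(c(m$clade, m$src, m$dest), focal_clade)) > 0L,
    logical(1)))
  if (primary_rec$cost < dl$cost - 1e-9 && focal_move) {
    res$category <- "lgt"
    res$donor <- assign_donor(primary_rec, species, taxonomy,
                              focal_clade = focal_clade)
    into <- transfers_into_focal(primary_rec, sidx, focal_clade)
    ends <- c(into$recipient,
              rec_focal_donor(primary_rec, sidx, focal_clade)$donor)
    res$pre_diversification <- any(vapply(ends, function(r)
      setequal(species_set_of(sidx, r), focal_clade), logical(1)))
  } else {
    res$category <- "conflicting"
  }
  structure(res, class = "family_classification")
}

#' @export
print.family_classification <- function(x, ...) {
  cat(sprintf("family %s: %s\n", x$family %||% "?", x$category))
  print(x$per_ratio, row.names = FALSE)
  if (length(x$donor)) cat("donor lineage:", paste(x$donor, collapse = "; "),
                           "\n")
  if (x$pre_diversification)
    cat("transfer predates the diversification of the focal clade\n")
  invisible(x)
}

#' Summarize transfer donors at the smallest covering taxonomic rank
#'
#' For each transfer into the focal clade, the donor edge's subtended
#' species set is reduced to the smallest rank (species < genus < order <
#' class) containing all of them; a transfer from the species-root edge (or
#' a donor set spanning several classes) is reported as
#' `"unresolved (root)"`.
#'
#' @param rec a `reconciliation` with >= 0 transfer events.
#' @param species the species tree.
#' @param taxonomy data.frame with columns `species`, `genus`, `order`,
#'   `class` covering every species (or `NULL` to report raw edge names).
#' @param focal_clade species ids; only transfers whose recipient subtends a
#'   focal species are summarized (`NULL` = all transfers).
#' @return character vector, one donor lineage per transfer.
#' @export
assign_donor <- function(rec, species, taxonomy = NULL, focal_clade = NULL) {
  sidx <- species_index(species)
  if (!is.null(taxonomy)) {
    absent <- setdiff(sidx$tip_label, taxonomy$species)
    if (length(absent))
      stop2("taxonomy lacks species: ", paste(absent, collapse = ", "))
  }
  if (is.null(focal_clade)) {
    tr <- rec$events[rec$events$kind == "transfer", , drop = FALSE]
    partners <- tr$donor
  } else {
    into <- transfers_into_focal(rec, sidx, focal_clade)
    outof <- rec_focal_donor(rec, sidx, focal_clade)
    # parsimony cannot orient a transfer: when only the inferred donor side
    # touches the focal clade, the non-focal recipient is the putative donor
    partners <- c(into$donor, outof$recipient)
  }
  if (!length(partners)) return(character(0))
  root_name <- node_name(sidx, sidx$root)
  vapply(partners, function(d) {
    if (d == root_name) return("unresolved (root)")
    tips <- species_set_of(sidx, d)
    if (is.null(taxonomy)) {
      if (length(tips) == 1L) return(tips)
      return(d)
    }
    missing <- setdiff(tips, taxonomy$species)
    if (length(missing))
      stop2("taxonomy lacks species: ", paste(missing, collapse = ", "))
    if (length(tips) == 1L) return(tips)
    rows <- taxonomy[match(tips, taxonomy$species), , drop = FALSE]
    for (rank in c("genus", "order", "class")) {
      if (length(unique(rows[[rank]])) == 1L)
        return(paste0(rank, ":", rows[[rank]][1L]))
    }
    "unresolved (root)"
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate family classifications into the category summary
#'
#' Counts families per category and converts them to nearest-integer
#' percentages (halves round up), plus a donor-lineage frequency table
#' sorted by decreasing count.
#'
#' @param classifications a non-empty list of `family_classification`
#'   objects, or `NULL` when `counts` is given directly.
#' @param counts optional named integer vector of per-category counts (the
#'   worked-arithmetic entry point: any category names are allowed).
#' @return an object of class `lgt_summary`: `total`, `counts`,
#'   `percentages` and `donors`.
#' @export
summarize_classification <- function(classifications = NULL, counts = NULL) {
  donors <- character(0)
  if (is.null(counts)) {
    if (!length(classifications)) stop2("no classifications to summarize")
    cats <- vapply(classifications, function(x) x$category, character(1))
    counts <- table(cats)
    counts <- stats::setNames(as.integer(counts), names(counts))
    donors <- unlist(lapply(classifications, function(x)
      if (identical(x$category, "lgt")) x$donor else character(0)))
  } else if (!length(counts) || sum(counts) == 0) {
    stop2("counts must be a non-empty named vector")
  }
  total <- sum(counts)
  pct <- round_half_up(100 * counts / total)
  donor_tab <- if (length(donors)) {
    tb <- table(donors)
    tb <- tb[order(-as.integer(tb), names(tb))]
    data.frame(donor = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(donor = character(0), n = integer(0))
  structure(list(total = total,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 percentages = stats::setNames(as.numeric(pct),
                                               names(counts)),
                 donors = donor_tab),
            class = "lgt_summary")
}

#' @export
print.lgt_summary <- function(x, ...) {
  cat("families:", x$total, "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %4d  (%d%%)\n", nm, x$counts[[nm]],
                as.integer(x$percentages[[nm]])))
  if (nrow(x$donors)) {
    cat("donor lineages:\n")
    for (i in seq_len(nrow(x$donors)))
      cat(sprintf("  %-24s %d\n", x$donors$donor[i], x$donors$n[i]))
  }
  invisible(x)
}
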