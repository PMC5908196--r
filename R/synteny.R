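# Flanking-gene synteny scoring between genomes.

#' Synteny score of an orthologous gene pair from its flanking genes
#'
#' Over the `2*flank` genes flanking the focal gene in genome A (`flank` on
#' each side), the score is the percentage that have an ortholog among the
#' focal ortholog's flanks in genome B *in conserved order*, where order
#' conservation is measured as the longest order-preserving (strictly
#' increasing) matching of flank positions; an inversion breaks the order.
#' A pair scores 100 iff all flanking genes are orthologous and their order
#' is conserved.
#'
#' @param gene_a,gene_b the focal orthologous gene ids in genomes A and B.
#' @param hood_a,hood_b ordered gene-id vectors (1-based gene ranks along a
#'   scaffold) containing the focal genes.
#' @param orthologs two-column data.frame (`a`, `b`) of ortholog pairs; the
#'   map is read symmetrically.
#' @param flank number of flanking genes per side (default 5).
#' @return the score in `[0, 100]`; attribute `truncated` is `TRUE` when
#'   fewer than `flank` genes were available on some side (the score is then
#'   over the available positions).
#' @export
synteny_score <- function(gene_a, gene_b, hood_a, hood_b, orthologs,
                          flank = 5L) {
  ia <- match(gene_a, hood_a)
  ib <- match(gene_b, hood_b)
  if (is.na(ia)) stop2("focal gene ", gene_a, " absent from its neighborhood")
  if (is.na(ib)) stop2("focal gene ", gene_b, " absent from its neighborhood")
  left <- seq(max(1L, ia - flank), ia - 1L)
  right <- seq(ia + 1L, min(length(hood_a), ia + flank))
  left <- left[left >= 1L & left < ia]
  right <- right[right > ia & right <= length(hood_a)]
  positions <- c(left, right)
  truncated <- length(positions) < 2L * flank
  if (!length(positions))
    return(structure(0, truncated = truncated))
  # map each flank gene of A to its ortholog (either column orientation)
  counterpart <- function(g) {
    hit <- orthologs$b[match(g, orthologs$a)]
    if (is.na(hit)) hit <- orthologs$a[match(g, orthologs$b)]
    hit
  }
  bwin <- seq(max(1L, ib - flank), min(length(hood_b), ib + flank))
  bwin <- bwin[bwin != ib]
  bpos <- vapply(hood_a[positions], function(g) {
    cp <- counterpart(g)
    if (is.na(cp)) return(NA_integer_)
    p <- match(cp, hood_b)
    if (is.na(p) || !(p %in% bwin)) NA_integer_ else p
  }, integer(1))
  seqs <- bpos[!is.na(bpos)]
  lis <- longest_increasing(seqs)
  structure(100 * lis / length(positions), truncated = truncated)
}

# length of the longest strictly increasing subsequence
longest_increasing <- function(x) {
  n <- length(x)
  if (!n) return(0L)
  best <- rep(1L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (x[j] < x[i] && best[j] + 1L > best[i]) best[i] <- best[j] + 1L
  max(best)
}

#' Test whether a gene cluster is synteny-conserved
#'
#' A cluster counts as conserved iff the fraction of conserved flanking-gene
#' positions across its members - the mean of the per-gene synteny
#' percentages - strictly exceeds the cutoff (default 80%).
#'
#' @param scores numeric vector of per-gene synteny percentages (named by
#'   gene id), one entry per cluster member.
#' @param cutoff percentage cutoff, strict (default 80).
#' @return `TRUE`/`FALSE`.
#' @export
cluster_synteny_test <- function(scores, cutoff = 80) {
  if (!length(scores)) stop2("empty cluster")
  mean(as.numeric(scores)) > cutoff
}

#' Read gene-order tables
#'
#' @param path TSV file with columns `genome`, `scaffold`, `rank`, `gene`.
#' @return named list (per genome) of gene-id vectors ordered by scaffold
#'   then rank.
#' @export
read_gene_orders <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome", "scaffold", "rank", "gene")
  if (!all(need %in% names(df)))
    stop2("gene-order table needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$genome, df$scaffold, df$rank), ]
  split(df$gene, df$genome)
}
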