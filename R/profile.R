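# Gene-family count-matrix analytics: clustering, ordination, genome share.

#' Read/write a species x family count matrix
#'
#' @param path TSV file; first column = species labels, remaining columns =
#'   family counts.
#' @return an integer matrix with species row names.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  validate_count_matrix(m)
  m
}

#' @rdname read_count_matrix
#' @param m the matrix to write.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(m) {
  if (any(m < 0, na.rm = TRUE)) stop2("counts must be non-negative")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop2("row/column labels must be unique")
  invisible(m)
}

#' Hierarchically cluster species by family-count profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage.
#' Rows are sorted lexicographically by label before clustering, making the
#' result invariant to input row order (deterministic tie-break).
#'
#' @param m a count matrix (>= 2 rows).
#' @return an [stats::hclust] object (merge list with heights).
#' @export
cluster_rows <- function(m) {
  validate_count_matrix(m)
  if (nrow(m) < 2L) stop2("need at least 2 rows to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
}

#' Principal-component coordinates of species count profiles
#'
#' PCA of the column-centered (optionally unit-variance scaled) count
#' matrix. Coordinates reproduce the best rank-`k` approximation of the
#' centered matrix; explained-variance fractions are non-increasing.
#'
#' @param m a count matrix.
#' @param k number of components (<= min(rows, cols)).
#' @param scale. scale columns to unit variance (default `FALSE`,
#'   center-only).
#' @return a list: `coords` (species x k), `explained` (fractions, length
#'   k), `rotation` (orthonormal loadings).
#' @export
pca_coords <- function(m, k = 2L, scale. = FALSE) {
  validate_count_matrix(m)
  if (k > min(dim(m))) stop2("k must be <= min(rows, cols)")
  totvar <- sum(apply(m, 2L, stats::var))
  if (totvar == 0) {
    coords <- matrix(0, nrow(m), k,
                     dimnames = list(rownames(m), paste0("PC", seq_len(k))))
    return(list(coords = coords, explained = rep(0, k),
                rotation = matrix(0, ncol(m), k)))
  }
  if (scale.) {
    sds <- apply(m, 2L, stats::sd)
    m <- m[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  k_eff <- min(k, ncol(p$x))
  coords <- p$x[, seq_len(k_eff), drop = FALSE]
  if (k_eff < k)
    coords <- cbind(coords, matrix(0, nrow(m), k - k_eff))
  colnames(coords) <- paste0("PC", seq_len(k))
  explained <- (p$sdev^2 / sum(p$sdev^2))[seq_len(k_eff)]
  explained <- c(explained, rep(0, k - k_eff))
  list(coords = coords, explained = explained,
       rotation = p$rotation[, seq_len(k_eff), drop = FALSE])
}

#' Share of a genome devoted to a gene set
#'
#' @param pcwd_count number of genes in the set (e.g. the plant cell
#'   wall-degrading CAZome of one species).
#' @param total_genes total gene count of the genome (> 0).
#' @return `100 * pcwd_count / total_genes`, rounded to one decimal
#'   (half up).
#' @export
genome_fraction <- function(pcwd_count, total_genes) {
  if (!is_scalar_number(total_genes) || total_genes <= 0)
    stop2("total_genes must be > 0")
  if (pcwd_count < 0 || pcwd_count > total_genes)
    stop2("pcwd_count must lie in [0, total_genes]")
  round_half_up(100 * pcwd_count / total_genes, 1L)
}
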