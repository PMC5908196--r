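# Tajima's D and the phylogenomic-marker selection filter.

#' Read an aligned FASTA file as a site matrix
#'
#' @param path path to an aligned (equal-length) nucleotide FASTA file.
#' @return a character matrix, sequences in rows, aligned columns.
#' @export
read_alignment_fasta <- function(path) {
  m <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  toupper(m)
}

# keep biallelic gap-free columns; return per-column minor/major counts
usable_columns <- function(sites) {
  n <- nrow(sites)
  if (is.numeric(sites)) {
    states <- apply(sites, 2L, function(col) length(unique(col)))
    keep <- which(states <= 2L)
    counts <- vapply(keep, function(j) sum(sites[, j] == sites[1L, j]),
                     integer(1))
  } else {
    good <- c("A", "C", "G", "T")
    keep <- integer(0)
    counts <- integer(0)
    for (j in seq_len(ncol(sites))) {
      col <- toupper(sites[, j])
      if (!all(col %in% good)) next
      alleles <- unique(col)
      if (length(alleles) > 2L) next
      keep <- c(keep, j)
      counts <- c(counts, sum(col == alleles[1L]))
    }
  }
  list(n = n, n1 = counts, n2 = nrow(sites) - counts)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Contrasts mean pairwise nucleotide diversity (pi) with the scaled number
#' of segregating sites (S/a1):
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))`
#' with the usual constants `a1, a2, b1, b2, c1, c2, e1, e2` as functions of
#' the sample size. Columns containing gaps/ambiguities or more than two
#' alleles are excluded from both S and pi (infinite-sites assumption).
#'
#' @param sites a site matrix: either a binary 0/1 haplotype matrix or a
#'   character nucleotide alignment; rows are sequences.
#' @return the value of D, or `NA` (undefined) when `S = 0` or the variance
#'   term vanishes.
#' @export
tajimas_d <- function(sites) {
  if (!is.matrix(sites) || nrow(sites) < 2L)
    stop2("need a site matrix with at least 2 sequences")
  u <- usable_columns(sites)
  n <- u$n
  poly <- u$n1 > 0L & u$n2 > 0L
  S <- sum(poly)
  if (S == 0L) return(NA_real_)
  pi_hat <- sum(u$n1[poly] * u$n2[poly]) / (n * (n - 1) / 2)
  k <- tajima_constants(n)
  num <- pi_hat - S / k$a1
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 1e-12) {
    # degenerate variance (n = 3 has c1 = c2 = 0 exactly): D is 0 in the
    # limit when the numerator also vanishes, undefined otherwise
    return(if (abs(num) < 1e-9) 0 else NA_real_)
  }
  num / sqrt(v)
}

# Tajima's beta-approximation limits of D for sample size n: the statistic
# is bounded, and a scaled beta with mean 0 and variance 1 on [dmin, dmax]
# approximates its null distribution.
tajima_d_range <- function(n) {
  k <- tajima_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  pi_max <- if (n %% 2 == 0) n / (2 * (n - 1)) else (n + 1) / (2 * n)
  dmax <- (pi_max - 1 / k$a1) / sqrt(k$e2)
  c(dmin, dmax)
}

#' Classify a Tajima's D value as neutral or not
#'
#' Two-sided test against the beta-distribution approximation of the null
#' distribution of D (mean 0, variance 1, supported on the theoretical
#' [Dmin, Dmax] for the sample size). `NA` (undefined) values propagate.
#'
#' @param d a D value (possibly `NA`).
#' @param n the sample size it was computed from.
#' @param alpha two-sided significance level, default 0.05.
#' @return `"neutral"`, `"non-neutral"` or `"undefined"`.
#' @export
neutrality_classify <- function(d, n, alpha = 0.05) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    stop2("alpha must be in (0, 1)")
  if (is.na(d)) return("undefined")
  rng <- tajima_d_range(n)
  a <- rng[1L]; b <- rng[2L]
  shape_common <- 1 + a * b            # negative when the approximation holds
  alpha_par <- -shape_common * b / (b - a)
  beta_par <- shape_common * a / (b - a)
  if (!is.finite(alpha_par) || !is.finite(beta_par) ||
      alpha_par <= 0 || beta_par <= 0) {
    return(if (abs(d) < 2) "neutral" else "non-neutral")
  }
  lo <- a + (b - a) * stats::qbeta(alpha / 2, beta_par, alpha_par)
  hi <- a + (b - a) * stats::qbeta(1 - alpha / 2, beta_par, alpha_par)
  if (d < lo || d > hi) "non-neutral" else "neutral"
}

#' Select phylogenomic marker genes
#'
#' Keeps candidates that are syntenic in all genomes, have no off-target
#' paralog above the amino-acid similarity cutoff (strictly greater than the
#' cutoff excludes), and whose Tajima's D classifies as neutral.
#'
#' @param candidates a data.frame with columns `gene`, `syntenic` (logical),
#'   `similarity` (max off-target amino-acid similarity, fraction) and
#'   `classification` (from [neutrality_classify()]).
#' @param similarity_cutoff default 0.50.
#' @return the retained rows of `candidates`.
#' @export
select_markers <- function(candidates, similarity_cutoff = 0.50) {
  assert_fraction(similarity_cutoff, "similarity_cutoff")
  need <- c("gene", "syntenic", "similarity", "classification")
  if (!all(need %in% names(candidates)))
    stop2("candidates must have columns: ", paste(need, collapse = ", "))
  keep <- candidates$syntenic &
    candidates$similarity <= similarity_cutoff &
    candidates$classification == "neutral"
  candidates[keep, , drop = FALSE]
}
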