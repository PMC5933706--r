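#' Derived site-frequency spectrum of a haplotype set
#'
#' @param x a [haplotype_matrix()].
#' @param rows optional haplotype row subset.
#' @param sites optional site column subset.
#' @return Integer vector of length n-1: number of sites with derived count
#'   i, for i = 1..n-1 (fixed and absent classes excluded).
#' @export
sfs_from_matrix <- function(x, rows = NULL, sites = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  sub <- x$alleles[rows, sites, drop = FALSE]
  n <- nrow(sub)
  counts <- colSums(sub)
  tabulate(counts[counts > 0 & counts < n], nbins = n - 1)
}

#' Nucleotide diversity (mean pairwise differences)
#'
#' Average number of differences over all haplotype pairs, computed from
#' per-site allele counts: sum over sites of k(n-k) / C(n,2).
#'
#' @inheritParams sfs_from_matrix
#' @return Scalar mean pairwise difference count.
#' @export
nucleotide_diversity <- function(x, rows = NULL, sites = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  sub <- x$alleles[rows, sites, drop = FALSE]
  n <- nrow(sub)
  if (n < 2) stop("need at least two haplotypes")
  k <- colSums(sub)
  sum(k * (n - k)) / choose(n, 2)
}

#' Tajima's D
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1)) with the standard Tajima
#' (1989) constants.
#'
#' @param S number of segregating sites.
#' @param pi mean pairwise differences.
#' @param n number of haplotypes.
#' @return Scalar D; `NA` when S = 0 (undefined, not zero).
#' @export
tajimas_d <- function(S, pi, n) {
  if (n < 4) stop("need at least 4 haplotypes")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D from a haplotype matrix
#'
#' @inheritParams sfs_from_matrix
#' @return Scalar D (`NA` if no segregating site in the subset).
#' @export
tajimas_d_matrix <- function(x, rows = NULL, sites = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  sub <- x$alleles[rows, sites, drop = FALSE]
  n <- nrow(sub)
  k <- colSums(sub)
  seg <- k > 0 & k < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi <- sum(k[seg] * (n - k[seg])) / choose(n, 2)
  tajimas_d(S, pi, n)
}

#' Fay and Wu's H
#'
#' Unnormalized H = theta_pi - theta_H computed from the polarized derived
#' SFS: theta_pi = sum 2 S_i i (n-i) / (n(n-1)),
#' theta_H = sum 2 S_i i^2 / (n(n-1)). Requires ancestral-allele polarized
#' input; strongly negative values indicate an excess of high-frequency
#' derived alleles.
#'
#' @param sfs derived site-frequency spectrum, counts for i = 1..n-1.
#' @param n number of haplotypes.
#' @return Scalar H (0 for an empty spectrum).
#' @export
fay_wu_h <- function(sfs, n) {
  if (length(sfs) != n - 1)
    stop("sfs must have n-1 entries (polarized derived spectrum)")
  if (any(sfs < 0)) stop("negative SFS entry")
  i <- seq_len(n - 1)
  theta_pi <- sum(2 * sfs * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(2 * sfs * i^2) / (n * (n - 1))
  theta_pi - theta_h
}
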