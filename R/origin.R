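#' Split haplotypes by the allele carried at the focal site
#'
#' Partitions haplotype rows into derived-allele and ancestral-allele
#' carriers and computes all pairwise Hamming distances among the derived
#' rows over the analysis window, excluding the focal site itself.
#'
#' @param x a [haplotype_matrix()].
#' @param focal_site physical position of the focal SNP.
#' @param window optional `c(start, end)` physical window restricting the
#'   sites used for distances (default: all sites).
#' @return A `haplotype_split` list: `derived_rows`, `ancestral_rows`,
#'   `pairwise_diff` (symmetric integer matrix among derived rows),
#'   `median_diff` (per derived row, median distance to the other derived
#'   rows), `window_sites` (column indices used).
#' @export
split_by_focal_allele <- function(x, focal_site, window = NULL) {
  j0 <- site_index(x, focal_site)
  derived_rows <- which(x$alleles[, j0] == 1L)
  ancestral_rows <- which(x$alleles[, j0] == 0L)
  if (!length(derived_rows)) stop("no derived-allele carriers at the focal site")
  sites <- seq_along(x$positions)
  if (!is.null(window))
    sites <- sites[x$positions >= window[1] & x$positions <= window[2]]
  sites <- setdiff(sites, j0)
  sub <- x$alleles[derived_rows, sites, drop = FALSE]
  # Hamming distances via crossprod on 0/1 matrix
  ones <- sub %*% t(sub)
  zeros <- (1L - sub) %*% t(1L - sub)
  pd <- length(sites) - ones - zeros
  diag(pd) <- 0L
  med <- if (length(derived_rows) < 2) NA_real_ else
    vapply(seq_along(derived_rows), function(i)
      stats::median(pd[i, -i]), numeric(1))
  structure(list(derived_rows = derived_rows, ancestral_rows = ancestral_rows,
                 pairwise_diff = pd, median_diff = med,
                 window_sites = sites, matrix = x),
            class = "haplotype_split")
}

#' Flag putatively recombinant derived haplotypes
#'
#' Derived-allele haplotypes whose median pairwise distance to the other
#' derived haplotypes exceeds `threshold` are flagged as putatively shaped
#' by recombination with the ancestral-allele background.
#'
#' @param split a [split_by_focal_allele()] result.
#' @param threshold median pairwise-difference cutoff (default 10).
#' @return Integer vector of flagged haplotype row indices (possibly empty).
#' @export
flag_recombinant_haplotypes <- function(split, threshold = 10) {
  stopifnot(inherits(split, "haplotype_split"))
  if (length(split$derived_rows) < 2) stop("need at least 2 derived rows")
  split$derived_rows[split$median_diff > threshold]
}

#' Proportion of distinguishing alleles shared with the ancestral background
#'
#' For the flagged (putatively recombinant) derived haplotypes, identifies
#' the alleles that distinguish them from the consensus of the unflagged
#' derived haplotypes, and reports which fraction of those alleles is also
#' observed on at least one ancestral-background haplotype. Values near 1
#' indicate the flagged haplotypes were assembled by recombination with the
#' ancestral class rather than by new mutation.
#'
#' @param split a [split_by_focal_allele()] result.
#' @param flagged haplotype row indices from [flag_recombinant_haplotypes()].
#' @return Proportion in [0, 1].
#' @export
ancestral_sharing_proportion <- function(split, flagged) {
  stopifnot(inherits(split, "haplotype_split"))
  if (!length(flagged)) stop("empty flagged set")
  x <- split$matrix
  sites <- split$window_sites
  keep <- setdiff(split$derived_rows, flagged)
  if (!length(keep)) stop("no unflagged derived haplotypes for the consensus")
  consensus <- as.integer(colMeans(
    x$alleles[keep, sites, drop = FALSE]) >= 0.5)
  anc <- x$alleles[split$ancestral_rows, sites, drop = FALSE]
  n_dist <- 0L; n_shared <- 0L
  for (row in flagged) {
    hap <- x$alleles[row, sites]
    diff_sites <- which(hap != consensus)
    for (s in diff_sites) {
      n_dist <- n_dist + 1L
      if (any(anc[, s] == hap[s])) n_shared <- n_shared + 1L
    }
  }
  if (n_dist == 0L) stop("flagged haplotypes do not differ from the consensus")
  n_shared / n_dist
}

#' Linked diversity among derived haplotypes before and after recombinant
#' filtering
#'
#' Per population: nucleotide diversity (mean pairwise differences) among
#' derived-allele haplotypes, raw and after removing haplotypes flagged by
#' the median-pairwise-difference rule. Populations with fewer than 2
#' surviving haplotypes get `NA`.
#'
#' @param x a [haplotype_matrix()] containing >= 1 population.
#' @param focal_site physical position of the focal SNP.
#' @param threshold recombinant flagging threshold (default 10).
#' @param window optional physical window (see [split_by_focal_allele()]).
#' @return data.frame with population, n_derived, n_removed, pi_raw,
#'   pi_filtered.
#' @export
filtered_linked_diversity <- function(x, focal_site, threshold = 10,
                                      window = NULL) {
  pops <- unique(x$population)
  res <- lapply(pops, function(p) {
    rows <- which(x$population == p)
    sub <- hm_subset(x, rows)
    j0 <- site_index(sub, focal_site)
    der <- which(sub$alleles[, j0] == 1L)
    if (length(der) < 2)
      return(data.frame(population = p, n_derived = length(der),
                        n_removed = 0L, pi_raw = NA_real_,
                        pi_filtered = NA_real_))
    split <- split_by_focal_allele(sub, focal_site, window)
    flagged <- flag_recombinant_haplotypes(split, threshold)
    survivors <- setdiff(split$derived_rows, flagged)
    pi_raw <- nucleotide_diversity(sub, rows = split$derived_rows,
                                   sites = split$window_sites)
    pi_f <- if (length(survivors) >= 2)
      nucleotide_diversity(sub, rows = survivors,
                           sites = split$window_sites) else NA_real_
    data.frame(population = p, n_derived = length(der),
               n_removed = length(flagged), pi_raw = pi_raw,
               pi_filtered = pi_f, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank populations by filtered linked diversity to infer allele origin
#'
#' The population with the highest filtered diversity among derived-allele
#' haplotypes is reported as the inferred origin (oldest local history of
#' the allele). Ties are reported explicitly.
#'
#' @param diversity a [filtered_linked_diversity()] table.
#' @return List with `ranking` (the table sorted by pi_filtered,
#'   descending), `origin` (top population label(s)), `tie` (logical).
#' @export
infer_origin <- function(diversity) {
  d <- diversity[!is.na(diversity$pi_filtered), , drop = FALSE]
  if (nrow(d) < 1) stop("no population with defined filtered diversity")
  d <- d[order(-d$pi_filtered), , drop = FALSE]
  top <- d$population[d$pi_filtered == d$pi_filtered[1]]
  list(ranking = d, origin = top, tie = length(top) > 1)
}
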