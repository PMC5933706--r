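#' Per-population allele counts at one site
#'
#' @param n diploid sample sizes, one per population.
#' @param derived_count derived allele counts (0..2n) per population.
#' @param het_count observed heterozygote counts per population, or `NULL`
#'   to impute heterozygosity under Hardy-Weinberg equilibrium, 2p(1-p)
#'   (used when only allele frequencies are available).
#' @return A `site_counts` object.
#' @export
site_counts <- function(n, derived_count, het_count = NULL) {
  n <- as.numeric(n); derived_count <- as.numeric(derived_count)
  if (length(n) != length(derived_count)) stop("length mismatch")
  if (any(derived_count < 0 | derived_count > 2 * n))
    stop("derived_count outside [0, 2n]")
  if (!is.null(het_count) && any(het_count < 0 | het_count > n))
    stop("het_count outside [0, n]")
  structure(list(n = n, derived_count = derived_count, het_count = het_count),
            class = "site_counts")
}

#' Weir-Cockerham variance components at a single site
#'
#' Computes the Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), and theta = a/(a+b+c), for r >= 2 populations with unequal
#' sample sizes via n_c. When heterozygote counts are unavailable the
#' observed heterozygosity is imputed under Hardy-Weinberg, 2p(1-p).
#'
#' @param counts a [site_counts()] object.
#' @return A list of class `fst_components` with `a`, `b`, `c`, `theta`
#'   (`theta` is `NA` and `defined` is `FALSE` when a+b+c = 0, i.e. the site
#'   is monomorphic across populations).
#' @export
wc_fst_site <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  n <- counts$n
  r <- length(n)
  if (r < 2) stop("need at least two populations")
  p <- counts$derived_count / (2 * n)
  h <- if (is.null(counts$het_count)) 2 * p * (1 - p) else counts$het_count / n
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  structure(list(a = a, b = b, c = cc,
                 theta = if (tot == 0) NA_real_ else a / tot,
                 defined = tot != 0),
            class = "fst_components")
}

# Vectorized two-population W&C components from allele frequencies under
# HWE heterozygosity. p1, p2 are per-site frequency vectors; n1, n2 diploid
# sample sizes. Returns list(a, total) per site.
wc_components_pair <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, total = a + b + cc)
}

#' Genome-wide F_ST as the ratio of averages
#'
#' Sum of among-population components over the sum of total components,
#' across sites: sum(a) / sum(a+b+c). This is the "ratio of averages", not
#' the mean of per-site theta. Sites with undefined components (monomorphic
#' in the pair) are excluded.
#'
#' @param components a list of [wc_fst_site()] results, or a list with
#'   vectors `a` and `total` as produced internally for site batches.
#' @return Scalar F_ST estimate.
#' @export
fst_ratio_of_averages <- function(components) {
  if (is.list(components) && !is.null(components$a)) {
    a <- components$a; tot <- components$total
  } else {
    if (!length(components)) stop("empty component list")
    a <- vapply(components, function(z) z$a, numeric(1))
    tot <- vapply(components, function(z) z$a + z$b + z$c, numeric(1))
  }
  keep <- is.finite(a) & is.finite(tot) & tot != 0
  if (!any(keep)) stop("no site with defined components")
  sum(a[keep]) / sum(tot[keep])
}

#' Pairwise ratio-of-averages F_ST matrix from population frequencies
#'
#' For each population pair, F_ST is the ratio of averages over the sites
#' polymorphic in that pair.
#'
#' @param freq matrix of derived allele frequencies, populations in rows,
#'   sites in columns; row names are population labels.
#' @param n diploid sample sizes per population.
#' @return Symmetric matrix of pairwise F_ST (diagonal 0).
#' @export
pairwise_fst_matrix <- function(freq, n) {
  pops <- rownames(freq)
  if (is.null(pops)) pops <- paste0("pop", seq_len(nrow(freq)))
  r <- nrow(freq)
  out <- matrix(0, r, r, dimnames = list(pops, pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    poly <- freq[i, ] + freq[j, ] > 0 & freq[i, ] + freq[j, ] < 2
    comp <- wc_components_pair(freq[i, poly], freq[j, poly], n[i], n[j])
    out[i, j] <- out[j, i] <- sum(comp$a) / sum(comp$total)
  }
  out
}

#' Empirical P-value against a genome-wide background distribution
#'
#' Rank-based tail probability: for the upper tail, the proportion of
#' background values greater than or equal to the observed value. A value
#' exceeding the whole background yields p = 0, annotated as "< 1/N".
#'
#' @param value observed statistic.
#' @param background numeric vector of background values.
#' @param tail `"upper"` or `"lower"`.
#' @return The empirical P (with a `"label"` attribute such as `"<1e-04"`
#'   when the observation falls beyond the background).
#' @export
empirical_pvalue <- function(value, background, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  background <- background[is.finite(background)]
  if (!length(background)) stop("empty background")
  p <- if (tail == "upper") mean(background >= value) else mean(background <= value)
  if (p == 0)
    attr(p, "label") <- sprintf("< %g", 1 / length(background))
  p
}
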