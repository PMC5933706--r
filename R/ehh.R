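#' EHH decay and integrated haplotype homozygosity around a core site
#'
#' Extended haplotype homozygosity EHH(x) is the fraction of carrier pairs
#' that are identical over every site between the core and x (inclusive).
#' The curve is followed outward in both directions until it falls below
#' `cutoff` (or the region end), and iHH is the trapezoid integral of EHH
#' against genetic distance (cM), summed over both directions. The segment
#' reaching the first site below the cutoff is included, then integration
#' stops.
#'
#' @param x a [haplotype_matrix()].
#' @param core_site physical position of the core SNP.
#' @param core_allele 0 (ancestral), 1 (derived), or `NULL` to use all
#'   haplotypes (the cross-population EHH convention).
#' @param map a [genetic_map()].
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param rows optional haplotype row subset applied before carrier
#'   selection.
#' @return List with `ehh` (data.frame position/ehh over the followed
#'   span), `ihh` (scalar, `NA` with `defined = FALSE` when there are
#'   fewer than 2 carriers), `n_carriers`.
#' @export
ehh_and_ihh <- function(x, core_site, core_allele = NULL, map,
                        cutoff = 0.05, rows = NULL) {
  j0 <- site_index(x, core_site)
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  carriers <- if (is.null(core_allele)) rows else
    rows[x$alleles[rows, j0] == core_allele]
  if (length(carriers) < 2)
    return(list(ehh = NULL, ihh = NA_real_, defined = FALSE,
                n_carriers = length(carriers)))
  # monomorphic sites carry no haplotype information and must not alter
  # the integration grid
  k <- colSums(x$alleles)
  sites <- which((k > 0 & k < nrow(x$alleles)) |
                   seq_along(k) == j0)
  x <- hm_subset(x, sites = sites)
  j0 <- site_index(x, core_site)
  ehh <- ehh_curve_cpp(x$alleles[carriers, , drop = FALSE], j0)
  cm <- map_cm(map, x$positions)

  integrate_dir <- function(idx) {  # idx: site indices outward from core
    total <- 0
    for (k in seq_along(idx)[-1]) {
      a <- idx[k - 1]; b <- idx[k]
      total <- total + abs(cm[b] - cm[a]) * (ehh[a] + ehh[b]) / 2
      if (ehh[b] < cutoff) break
    }
    total
  }
  m <- length(ehh)
  ihh <- integrate_dir(j0:m) + integrate_dir(j0:1)
  keep <- which(!is.na(ehh))
  list(ehh = data.frame(position = x$positions[keep], ehh = ehh[keep]),
       ihh = ihh, defined = TRUE, n_carriers = length(carriers))
}

#' Unstandardized iHS at one site
#'
#' ln(iHH_ancestral / iHH_derived); negative values indicate unusually long
#' derived-allele haplotypes.
#'
#' @inheritParams ehh_and_ihh
#' @return Scalar, `NA` when either allele class has < 2 carriers or an
#'   iHH of zero.
#' @export
ihs_site <- function(x, core_site, map, cutoff = 0.05, rows = NULL) {
  d <- ehh_and_ihh(x, core_site, 1L, map, cutoff, rows)
  a <- ehh_and_ihh(x, core_site, 0L, map, cutoff, rows)
  if (!isTRUE(d$defined) || !isTRUE(a$defined)) return(NA_real_)
  if (d$ihh <= 0 || a$ihh <= 0) return(NA_real_)
  log(a$ihh / d$ihh)
}

#' iHS scan with frequency-bin standardization
#'
#' Computes unstandardized iHS at every site with derived allele frequency
#' inside `maf_bounds`, then standardizes to mean 0 / sd 1 within derived
#' allele frequency bins (default 2% bins) over the background set. Sites
#' outside the frequency bounds are reported as `NA`.
#'
#' @inheritParams ehh_and_ihh
#' @param maf_bounds derived-allele-frequency bounds, default c(0.05, 0.95).
#' @param bin_width DAF bin width for standardization (default 0.02).
#' @param background optional data.frame with columns `daf` and `ihs_unstd`
#'   providing the genome-wide standardization background; defaults to the
#'   scanned sites themselves.
#' @return data.frame with position, daf, ihs_unstd, ihs_std.
#' @export
ihs_scan <- function(x, map, maf_bounds = c(0.05, 0.95), cutoff = 0.05,
                     bin_width = 0.02, background = NULL) {
  daf <- derived_freq(x)
  eligible <- daf > maf_bounds[1] & daf < maf_bounds[2]
  unstd <- rep(NA_real_, length(daf))
  for (j in which(eligible))
    unstd[j] <- ihs_site(x, x$positions[j], map, cutoff)
  if (is.null(background))
    background <- data.frame(daf = daf[eligible], ihs_unstd = unstd[eligible])
  brk <- seq(0, 1, by = bin_width)
  bin <- cut(daf, brk, include.lowest = TRUE)
  bbin <- cut(background$daf, brk, include.lowest = TRUE)
  std <- rep(NA_real_, length(daf))
  for (lev in levels(bin)) {
    idx <- which(bin == lev & !is.na(unstd))
    if (!length(idx)) next
    bg <- background$ihs_unstd[bbin == lev & !is.na(background$ihs_unstd)]
    if (length(bg) < 2 || stats::sd(bg) == 0) {
      warning(sprintf("no usable background in DAF bin %s; iHS left NA", lev))
      next
    }
    std[idx] <- (unstd[idx] - mean(bg)) / stats::sd(bg)
  }
  data.frame(position = x$positions, daf = daf,
             ihs_unstd = unstd, ihs_std = std)
}

#' Unstandardized XP-EHH at one site
#'
#' ln(iHH_test / iHH_reference), with iHH computed from all haplotypes of
#' each panel from the core site outward. Positive values indicate longer
#' haplotypes in the test panel.
#'
#' @param x_test,x_ref [haplotype_matrix()] panels sharing the site set.
#' @inheritParams ehh_and_ihh
#' @return Scalar, `NA` when the reference iHH is 0.
#' @export
xpehh_site <- function(x_test, x_ref, core_site, map, cutoff = 0.05) {
  te <- ehh_and_ihh(x_test, core_site, NULL, map, cutoff)
  re <- ehh_and_ihh(x_ref, core_site, NULL, map, cutoff)
  if (!isTRUE(te$defined) || !isTRUE(re$defined)) return(NA_real_)
  if (re$ihh <= 0 || te$ihh <= 0) return(NA_real_)
  log(te$ihh / re$ihh)
}

#' XP-EHH scan with genome-wide standardization
#'
#' @inheritParams xpehh_site
#' @param min_test_daf sites with test-panel derived allele frequency at or
#'   below this are reported `NA` (default 0.05).
#' @param background optional numeric vector of unstandardized XP-EHH
#'   values for standardization; defaults to the scanned sites.
#' @return data.frame with position, daf_test, xpehh_unstd, xpehh_std.
#' @export
xpehh_scan <- function(x_test, x_ref, map, min_test_daf = 0.05,
                       cutoff = 0.05, background = NULL) {
  if (!identical(x_test$positions, x_ref$positions))
    stop("test and reference panels must share the site set")
  daf <- derived_freq(x_test)
  unstd <- rep(NA_real_, length(daf))
  for (j in which(daf > min_test_daf))
    unstd[j] <- xpehh_site(x_test, x_ref, x_test$positions[j], map, cutoff)
  if (is.null(background)) background <- unstd[!is.na(unstd)]
  std <- if (length(background) >= 2 && stats::sd(background, na.rm = TRUE) > 0)
    (unstd - mean(background, na.rm = TRUE)) /
      stats::sd(background, na.rm = TRUE) else rep(NA_real_, length(unstd))
  data.frame(position = x_test$positions, daf_test = daf,
             xpehh_unstd = unstd, xpehh_std = std)
}
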