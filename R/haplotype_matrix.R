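#' Phased haplotype matrix
#'
#' The central data container: a matrix of 0/1 alleles (0 = ancestral,
#' 1 = derived) with rows = haplotypes and columns = polymorphic sites.
#' Every diploid individual contributes two consecutive rows.
#'
#' @param alleles integer/numeric matrix of 0s and 1s, haplotypes in rows.
#' @param positions physical positions (1-based bp), strictly increasing,
#'   one per column.
#' @param sample_ids character vector of individual identifiers, one per
#'   haplotype row (each id appears exactly twice for phased diploids).
#' @param population character vector of population labels per haplotype row.
#'
#' @return An object of class `haplotype_matrix` with fields `alleles`,
#'   `positions`, `sample_ids` and `population`.
#' @export
haplotype_matrix <- function(alleles, positions, sample_ids, population) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  positions <- as.numeric(positions)
  sample_ids <- as.character(sample_ids)
  population <- as.character(population)
  if (ncol(alleles) != length(positions))
    stop("length(positions) must equal ncol(alleles)")
  if (nrow(alleles) != length(sample_ids) || nrow(alleles) != length(population))
    stop("sample_ids and population must have one entry per haplotype row")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  bad <- !(alleles %in% c(0L, 1L))
  if (any(bad))
    stop("alleles must be 0 (ancestral) or 1 (derived)")
  structure(
    list(alleles = alleles, positions = positions,
         sample_ids = sample_ids, population = population),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d individuals) x %d sites\n",
              nrow(x$alleles), length(unique(x$sample_ids)), ncol(x$alleles)))
  cat(sprintf("  span: %s-%s bp; populations: %s\n",
              format(min(x$positions)), format(max(x$positions)),
              paste(unique(x$population), collapse = ", ")))
  invisible(x)
}

#' @export
dim.haplotype_matrix <- function(x) dim(x$alleles)

#' Subset a haplotype matrix
#'
#' @param x a [haplotype_matrix()].
#' @param rows haplotype row indices (or logical mask) to keep.
#' @param sites site column indices (or logical mask) to keep.
#' @return The subsetted `haplotype_matrix`.
#' @export
hm_subset <- function(x, rows = NULL, sites = NULL) {
  stopifnot(inherits(x, "haplotype_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  if (is.null(sites)) sites <- seq_len(ncol(x$alleles))
  haplotype_matrix(x$alleles[rows, sites, drop = FALSE],
                   x$positions[sites],
                   x$sample_ids[rows],
                   x$population[rows])
}

#' Derived allele frequency per site
#'
#' @param x a [haplotype_matrix()].
#' @param rows optional haplotype row subset.
#' @return Numeric vector of derived allele frequencies, one per site.
#' @export
derived_freq <- function(x, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(x$alleles))
  colMeans(x$alleles[rows, , drop = FALSE])
}

#' Locate a site column by physical position
#'
#' @param x a [haplotype_matrix()].
#' @param position physical position (bp).
#' @return Integer column index.
#' @export
site_index <- function(x, position) {
  i <- match(position, x$positions)
  if (is.na(i)) stop(sprintf("no site at position %s", format(position)))
  i
}
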