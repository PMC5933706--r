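#' Read a phased VCF region into a haplotype matrix
#'
#' Parses a phased VCF 4.x file, keeps biallelic SNPs only, and polarizes
#' genotypes against the INFO/AA ancestral-allele annotation: a 1 means the
#' haplotype carries the derived allele. Sites whose AA is missing, `.`,
#' `N`, or not one of REF/ALT are treated as unpolarized and dropped, as are
#' indels and multiallelic records.
#'
#' @param path path to a VCF file (uncompressed or bgzipped).
#' @param region optional `"chrom:start-end"` string (1-based inclusive).
#' @param focal_site optional physical position that must be present after
#'   filtering; an error is raised if it is absent.
#' @param pop_map optional named character vector mapping sample id to
#'   population label; unmapped samples get `"pop1"`.
#' @return A [haplotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, focal_site = NULL, pop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  pos <- as.numeric(fix$POS)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- keep & fix$CHROM == m[2] &
      pos >= as.numeric(m[3]) & pos <= as.numeric(m[4])
  }
  # biallelic SNPs only
  keep <- keep & nchar(fix$REF) == 1 & !grepl(",", fix$ALT) &
    nchar(fix$ALT) == 1 & fix$ALT %in% c("A", "C", "G", "T") &
    fix$REF %in% c("A", "C", "G", "T")
  # ancestral-allele polarization
  aa <- toupper(substr(sub(".*AA=([^;]*).*", "\\1",
                           ifelse(grepl("AA=", fix$INFO), fix$INFO, "")), 1, 1))
  polarized <- aa %in% c("A", "C", "G", "T") &
    (aa == toupper(fix$REF) | aa == toupper(fix$ALT))
  keep <- keep & polarized

  if (!any(keep)) stop("no polarized biallelic SNPs retained")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  aa <- aa[keep]

  gt <- sub(":.*", "", gt)  # strip FORMAT fields beyond GT
  unphased <- matrix(grepl("/", gt), nrow(gt))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at %s:%s sample %s",
                 fix$CHROM[i[1]], fix$POS[i[1]], colnames(gt)[i[2]]))
  }
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  if (any(a1 == "." | a2 == "."))
    stop("missing genotypes are not supported in phased haplotype input")

  # derived allele index: 1 if REF is ancestral, 0 if ALT is ancestral
  derived_idx <- ifelse(aa == toupper(fix$REF), "1", "0")
  n_samp <- ncol(gt)
  alleles <- matrix(0L, nrow = 2 * n_samp, ncol = nrow(fix))
  for (j in seq_len(nrow(fix))) {
    alleles[seq(1, 2 * n_samp, by = 2), j] <- as.integer(a1[j, ] == derived_idx[j])
    alleles[seq(2, 2 * n_samp, by = 2), j] <- as.integer(a2[j, ] == derived_idx[j])
  }
  ids <- rep(colnames(gt), each = 2)
  pops <- if (is.null(pop_map)) rep("pop1", length(ids)) else {
    p <- unname(pop_map[ids]); p[is.na(p)] <- "pop1"; p
  }
  ord <- order(pos)
  hm <- haplotype_matrix(alleles[, ord, drop = FALSE], pos[ord], ids, pops)
  if (!is.null(focal_site) && !(focal_site %in% hm$positions))
    stop(sprintf("focal site %s absent from retained sites", format(focal_site)))
  hm
}

#' Write a haplotype matrix to a minimal phased VCF
#'
#' Ancestral alleles are written as REF with `AA=` set accordingly, so that
#' [read_vcf()] round-trips the matrix exactly.
#'
#' @param x a [haplotype_matrix()].
#' @param path output file path.
#' @param chrom chromosome label.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path, chrom = "2") {
  ids <- unique(x$sample_ids)
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  rows1 <- match(ids, x$sample_ids)
  rows2 <- vapply(ids, function(id) which(x$sample_ids == id)[2], integer(1))
  recs <- vapply(seq_along(x$positions), function(j) {
    gtv <- paste(x$alleles[rows1, j], x$alleles[rows2, j], sep = "|")
    paste(c(chrom, format(x$positions[j], scientific = FALSE), ".",
            "A", "G", ".", "PASS", "AA=A", "GT", gtv), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Down-sample each population to a fixed number of individuals
#'
#' Mirrors the equal-power design of scans that keep the same number of
#' unrelated individuals per population: each population is randomly
#' down-sampled to `n` individuals, keeping both haplotypes of every kept
#' individual. Deterministic given `seed`.
#'
#' @param x a [haplotype_matrix()].
#' @param n individuals to keep per population.
#' @param seed integer seed.
#' @return A [haplotype_matrix()] with exactly `n` individuals per population.
#' @export
downsample_individuals <- function(x, n, seed = 1L) {
  stopifnot(inherits(x, "haplotype_matrix"))
  by_pop <- split(x$sample_ids, x$population)
  counts <- vapply(by_pop, function(s) length(unique(s)), integer(1))
  short <- names(counts)[counts < n]
  if (length(short))
    stop(sprintf("populations with fewer than %d individuals: %s",
                 n, paste(short, collapse = ", ")))
  keep_ids <- local_seed(seed, {
    unlist(lapply(names(by_pop), function(p) {
      ids <- unique(by_pop[[p]])
      sort(sample(ids, n))
    }))
  })
  hm_subset(x, rows = x$sample_ids %in% keep_ids)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Recombination map
#'
#' Piecewise-constant genetic map. `rate[i]` (cM/Mb) applies on
#' `[pos[i], pos[i+1])`; the final rate extends beyond the last map point.
#' Cumulative map positions are recomputed by rectangular integration.
#'
#' @param pos physical positions (bp) of interval boundaries, increasing.
#' @param rate recombination rate (cM/Mb) per interval, one per position.
#' @return An object of class `genetic_map` with fields `pos`, `rate`,
#'   `cumulative` (cM at each boundary).
#' @export
genetic_map <- function(pos, rate) {
  pos <- as.numeric(pos); rate <- as.numeric(rate)
  if (length(pos) != length(rate)) stop("pos and rate lengths differ")
  if (length(pos) > 1 && any(diff(pos) <= 0)) stop("positions must increase")
  if (any(rate < 0)) stop("negative recombination rate")
  cumulative <- c(0, cumsum(rate[-length(rate)] * diff(pos) / 1e6))
  structure(list(pos = pos, rate = rate, cumulative = cumulative),
            class = "genetic_map")
}

#' Read a HapMap-format genetic map
#'
#' Three whitespace-delimited columns with header: position (bp), rate
#' (cM/Mb), cumulative map (cM). The cumulative column is recomputed from
#' the rates so the two are always consistent.
#'
#' @param path path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  if (ncol(d) < 2) stop("genetic map needs at least position and rate columns")
  genetic_map(d[[1]], d[[2]])
}

#' Cumulative genetic position (cM) at arbitrary physical positions
#'
#' @param map a [genetic_map()].
#' @param at physical positions (bp).
#' @return Numeric cM positions (rates extrapolated flat beyond map ends).
#' @export
map_cm <- function(map, at) {
  i <- findInterval(at, map$pos)
  i0 <- pmax(i, 1L)
  cm <- map$cumulative[i0] + map$rate[i0] * (at - map$pos[i0]) / 1e6
  cm
}

#' Average several genetic maps position-wise
#'
#' Computes the per-basepair arithmetic mean rate on the union of all
#' breakpoints over the shared span of the maps.
#'
#' @param maps list of [genetic_map()] objects.
#' @return A [genetic_map()] on the refined breakpoints.
#' @export
average_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  starts <- vapply(maps, function(m) m$pos[1], numeric(1))
  ends <- vapply(maps, function(m) m$pos[length(m$pos)], numeric(1))
  lo <- max(starts); hi <- min(ends)
  if (lo >= hi) stop("maps have disjoint spans")
  brk <- sort(unique(c(lo, hi, unlist(lapply(maps, function(m)
    m$pos[m$pos >= lo & m$pos <= hi])))))
  rate_at <- function(m, p) m$rate[pmax(findInterval(p, m$pos), 1L)]
  mean_rate <- rowMeans(vapply(maps, rate_at, numeric(length(brk)), p = brk))
  genetic_map(brk, mean_rate)
}

#' Read a population metadata table
#'
#' Delimited text with header; mandatory columns `population`, `latitude`,
#' `longitude`, `temperature`, `n_individuals` (optional
#' `fst_to_reference`). Southern-hemisphere latitudes are folded to their
#' absolute value.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator (default tab).
#' @return A data.frame, one row per population.
#' @export
read_population_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("population", "latitude", "longitude", "temperature",
            "n_individuals")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  d$latitude <- abs(d$latitude)
  if (any(d$latitude > 90)) stop("latitude outside [0, 90]")
  if (any(d$n_individuals < 1)) stop("n_individuals must be >= 1")
  d
}

#' Read a per-individual genotype table
#'
#' Delimited text with header; mandatory columns `individual_id`,
#' `population`, `derived_count`, `ancestral_count`, `latitude`; optional
#' `longitude`, `temperature`, `age_years`. Rows with missing genotype are
#' flagged in a logical `missing` column rather than dropped.
#'
#' @inheritParams read_population_table
#' @return A data.frame of genotype records.
#' @export
read_genotype_table <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("individual_id", "population", "derived_count",
            "ancestral_count", "latitude")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  d$missing <- is.na(d$derived_count) | is.na(d$ancestral_count)
  ok <- !d$missing
  if (any(d$derived_count[ok] + d$ancestral_count[ok] != 2))
    stop("derived_count + ancestral_count must equal 2 for diploids")
  d$latitude <- abs(d$latitude)
  d
}
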