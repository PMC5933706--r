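# Small builders shared across test files.

# A toy phased VCF: 3 samples, 5 SNPs. SNP at 300 has AA=. (unpolarized),
# SNP at 400 has AA equal to ALT (flipped polarization), SNP 500 is an indel.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1\t0|0",
    "2\t200\t.\tC\tT\t.\tPASS\tAA=C\tGT\t0|0\t0|1\t1|1",
    "2\t300\t.\tG\tA\t.\tPASS\tAA=.\tGT\t0|1\t0|0\t0|0",
    "2\t400\t.\tT\tC\t.\tPASS\tAA=C\tGT\t0|1\t0|0\t1|1",
    "2\t450\t.\tTA\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|1\t0|0",
    "2\t500\t.\tG\tC\t.\tPASS\tAA=G\tGT\t1|0\t0|0\t0|1")
  writeLines(lines, path)
  path
}

# haplotype matrix from a plain 0/1 matrix with default ids
toy_hm <- function(alleles, positions = NULL, population = NULL) {
  alleles <- as.matrix(alleles)
  n <- nrow(alleles)
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 100
  if (is.null(population)) population <- rep("pop1", n)
  haplotype_matrix(alleles, positions,
                   rep(sprintf("i%03d", seq_len(ceiling(n / 2))),
                       each = 2)[seq_len(n)],
                   population)
}

# A cheap synthetic "reference table" with the real column layout but
# Gaussian statistics, for exercising the ABC machinery without the locus
# simulator. Each model is a shifted Gaussian cloud in stat space.
toy_ref <- function(n_per_model, shift = c(SDN = 3, SSV = 0, NTR = -3),
                    sd = 1, seed = 1) {
  set.seed(seed)
  stat_names <- c("xpehh_core", "tajd_afr_central", "fwh_afr_central",
                  "tajd_afr_flanks", "fwh_afr_flanks", "tajd_nonafr_central",
                  "fwh_nonafr_central", "tajd_nonafr_flanks",
                  "fwh_nonafr_flanks", "fst_central", "fst_flanks",
                  "daf_afr", "daf_nonafr", "fst_focal")
  do.call(rbind, lapply(names(shift), function(m) {
    X <- matrix(rnorm(n_per_model * 14, shift[m], sd), n_per_model, 14,
                dimnames = list(NULL, stat_names))
    cbind(data.frame(model = m,
                     t_sel = runif(n_per_model, 21000, 60000),
                     s_A = runif(n_per_model, 0, 0.015),
                     s_NA = X[, 1] * 0.005 + 0.02,  # encoded in stat 1
                     f_sel = runif(n_per_model, 0, 0.2)),
          as.data.frame(X))
  }))
}

# independent literal transcription of the Weir & Cockerham (1984)
# variance components, kept deliberately separate from the package code
wc_oracle <- function(n, p, h) {
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}
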