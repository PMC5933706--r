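#' Scenario for a synthetic latitudinal cline
#'
#' Describes a sampling design in which the focal SNP's logit frequency is
#' linear in (z-scored) latitude and temperature, with Balding-Nichols
#' drift noise around the deterministic cline, plus unlinked neutral
#' background SNPs under the same drift model. Temperature defaults to a
#' noisy monotone-decreasing function of latitude, mimicking the
#' collinearity real cline regressions must disentangle.
#'
#' @param n_pops number of populations.
#' @param latitudes per-population latitudes (degrees); default equally
#'   spaced on 0..65.
#' @param temperatures per-population annual mean temperatures; default
#'   27 - 0.35 * latitude + N(0, temp_noise_sd).
#' @param temp_noise_sd sd of temperature noise around the lapse line.
#' @param beta_lat,beta_temp logit-scale effects per z-unit of predictor.
#' @param base_logit cline intercept on the logit scale.
#' @param drift_fst per-population Balding-Nichols F in (0,1) (recycled).
#' @param n_individuals diploid individuals per population.
#' @param n_background_snps unlinked neutral background SNPs.
#' @param seed integer seed.
#' @return A `cline_scenario` object.
#' @export
cline_scenario <- function(n_pops = 20, latitudes = NULL, temperatures = NULL,
                           temp_noise_sd = 2, beta_lat = 1, beta_temp = 0,
                           base_logit = 0, drift_fst = 0.02,
                           n_individuals = 61, n_background_snps = 1000,
                           seed = 1L) {
  if (is.null(latitudes)) latitudes <- seq(0, 65, length.out = n_pops)
  stopifnot(length(latitudes) == n_pops, n_individuals >= 2)
  drift_fst <- rep_len(drift_fst, n_pops)
  if (any(drift_fst <= 0 | drift_fst >= 1)) stop("drift_fst must be in (0,1)")
  if (is.null(temperatures))
    temperatures <- local_seed(seed + 101L,
      27 - 0.35 * latitudes + stats::rnorm(n_pops, 0, temp_noise_sd))
  structure(list(n_pops = n_pops, latitudes = latitudes,
                 temperatures = temperatures, beta_lat = beta_lat,
                 beta_temp = beta_temp, base_logit = base_logit,
                 drift_fst = drift_fst, n_individuals = n_individuals,
                 n_background_snps = n_background_snps, seed = seed),
            class = "cline_scenario")
}

# one Balding-Nichols draw per population around ancestral frequency p
rbalding_nichols <- function(p, F) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  stats::rbeta(length(F), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Generate a clinal focal-SNP panel
#'
#' Population frequencies follow
#' p_j = inv-logit(base_logit + beta_lat z(lat_j) + beta_temp z(temp_j))
#' perturbed by a Balding-Nichols draw with the population's drift F;
#' individual genotypes are Binomial(2, p_j).
#'
#' @param scenario a [cline_scenario()].
#' @return List with `records` (per-individual genotype data.frame in the
#'   [read_genotype_table()] layout) and `meta` (per-population table with
#'   realized frequency).
#' @export
generate_cline_panel <- function(scenario) {
  s <- scenario
  local_seed(s$seed, {
    eta <- s$base_logit + s$beta_lat * z_transform(s$latitudes) +
      s$beta_temp * z_transform(s$temperatures)
    p_det <- stats::plogis(eta)
    p <- rbalding_nichols(p_det, s$drift_fst)
    pops <- sprintf("P%02d", seq_len(s$n_pops))
    records <- do.call(rbind, lapply(seq_len(s$n_pops), function(j) {
      der <- stats::rbinom(s$n_individuals, 2, p[j])
      data.frame(individual_id = sprintf("%s_i%03d", pops[j],
                                         seq_len(s$n_individuals)),
                 population = pops[j], derived_count = der,
                 ancestral_count = 2L - der, latitude = s$latitudes[j],
                 longitude = 0, temperature = s$temperatures[j],
                 stringsAsFactors = FALSE)
    }))
    meta <- data.frame(population = pops, latitude = s$latitudes,
                       longitude = 0, temperature = s$temperatures,
                       n_individuals = s$n_individuals,
                       freq = as.numeric(tapply(records$derived_count,
                                                records$population, mean)) / 2,
                       stringsAsFactors = FALSE)
    list(records = records, meta = meta)
  })
}

#' Generate unlinked neutral background SNP frequencies
#'
#' Each SNP draws an ancestral frequency from Uniform(0.05, 0.95), then
#' independent per-population Balding-Nichols frequencies with the
#' population-specific drift F. The realized pairwise ratio-of-averages
#' F_ST matrix is returned alongside.
#'
#' @param scenario a [cline_scenario()].
#' @return List with `freq` (populations x SNPs frequency matrix),
#'   `counts` (sampled derived allele counts given 2n draws per SNP),
#'   `fst_matrix` (realized pairwise F_ST), `anc_freq`.
#' @export
generate_background <- function(scenario) {
  s <- scenario
  local_seed(s$seed + 1L, {
    m <- s$n_background_snps
    anc <- stats::runif(m, 0.05, 0.95)
    freq <- matrix(NA_real_, s$n_pops, m,
                   dimnames = list(sprintf("P%02d", seq_len(s$n_pops)), NULL))
    for (j in seq_len(s$n_pops))
      freq[j, ] <- stats::rbeta(m, anc * (1 - s$drift_fst[j]) / s$drift_fst[j],
                                (1 - anc) * (1 - s$drift_fst[j]) / s$drift_fst[j])
    counts <- matrix(stats::rbinom(length(freq), 2 * s$n_individuals, freq),
                     nrow = s$n_pops, dimnames = dimnames(freq))
    sample_freq <- counts / (2 * s$n_individuals)
    fst <- pairwise_fst_matrix(sample_freq,
                               rep(s$n_individuals, s$n_pops))
    out <- list(freq = freq, counts = counts, fst_matrix = fst,
                anc_freq = anc)
    attr(out, "n_individuals") <- s$n_individuals
    out
  })
}

#' Generate ancient genotype records along a frequency trajectory
#'
#' @param n number of ancient individuals.
#' @param age_range two-element vector of ages (years before present).
#' @param trajectory function mapping age (years) to derived allele
#'   frequency.
#' @param latitude_range two-element latitude range (degrees).
#' @param missing_rate proportion of individuals with missing genotype.
#' @param seed integer seed.
#' @return data.frame of genotype records with `age_years` and `missing`.
#' @export
generate_ancient_samples <- function(n, age_range = c(3000, 8500),
                                     trajectory = function(age) 0.75,
                                     latitude_range = c(38, 62),
                                     missing_rate = 0, seed = 1L) {
  local_seed(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])
    lats <- stats::runif(n, latitude_range[1], latitude_range[2])
    p <- vapply(ages, trajectory, numeric(1))
    if (any(p < 0 | p > 1)) stop("trajectory must map ages into [0,1]")
    der <- stats::rbinom(n, 2, p)
    miss <- stats::runif(n) < missing_rate
    der[miss] <- NA_integer_
    data.frame(individual_id = sprintf("anc%03d", seq_len(n)),
               population = "ancient", derived_count = der,
               ancestral_count = 2L - der, latitude = lats, longitude = 0,
               temperature = NA_real_, age_years = ages, missing = miss,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic country-level prevalence table
#'
#' prevalence = intercept + slope * DAF + Gaussian noise, clipped to [0,1].
#'
#' @param n_countries number of countries (ignored if `daf_values` given).
#' @param daf_values per-country derived allele frequencies in [0,1].
#' @param slope linear effect of DAF on prevalence.
#' @param noise_sd Gaussian noise sd.
#' @param intercept baseline prevalence.
#' @param seed integer seed.
#' @return data.frame with columns country, daf, prevalence.
#' @export
generate_prevalence_table <- function(n_countries = 8, daf_values = NULL,
                                      slope = 0.1, noise_sd = 0.02,
                                      intercept = 0.08, seed = 1L) {
  local_seed(seed, {
    if (is.null(daf_values))
      daf_values <- stats::runif(n_countries, 0.02, 0.9)
    if (any(daf_values < 0 | daf_values > 1)) stop("daf_values outside [0,1]")
    prev <- intercept + slope * daf_values +
      stats::rnorm(length(daf_values), 0, noise_sd)
    data.frame(country = sprintf("C%02d", seq_along(daf_values)),
               daf = daf_values,
               prevalence = pmin(pmax(prev, 0), 1))
  })
}
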