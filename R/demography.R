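#' Two-deme out-of-Africa demography (Gravel-style)
#'
#' Three-epoch African history (ancestral size, African expansion) with an
#' out-of-Africa bottleneck deme that grows exponentially after the
#' European/East-Asian split. Only the African deme and one non-African
#' branch are simulated; `branch` selects the European or East-Asian
#' daughter parameters. All values are the published point estimates of the
#' Gravel et al. out-of-Africa model and can be overridden.
#'
#' @param branch `"EUR"` or `"EAS"`.
#' @param generation_time years per generation (default 25).
#' @param n_anc ancestral effective size.
#' @param n_af African size after the expansion.
#' @param t_af_years time of the African expansion (years ago).
#' @param n_b out-of-Africa bottleneck size.
#' @param t_ooa_years time of the out-of-Africa split (years ago).
#' @param t_split_years time of the European/East-Asian split (years ago).
#' @param n_daughter0 daughter-deme size at the split.
#' @param growth per-generation exponential growth rate of the daughter.
#' @param m_af_b migration rate Africa <-> bottleneck deme (per gen).
#' @param m_af_daughter migration rate Africa <-> daughter deme (per gen).
#' @return A `demography` object with per-generation size vectors (index 1
#'   = present generation 0) for both demes, migration rates, and the
#'   ancient constant size.
#' @export
gravel_demography <- function(branch = c("EUR", "EAS"),
                              generation_time = 25,
                              n_anc = 7310, n_af = 14474,
                              t_af_years = 148000, n_b = 1861,
                              t_ooa_years = 51000, t_split_years = 23000,
                              n_daughter0 = NULL, growth = NULL,
                              m_af_b = 15e-5, m_af_daughter = NULL) {
  branch <- match.arg(branch)
  if (is.null(n_daughter0)) n_daughter0 <- if (branch == "EUR") 1032 else 554
  if (is.null(growth)) growth <- if (branch == "EUR") 0.0038 else 0.0048
  if (is.null(m_af_daughter))
    m_af_daughter <- if (branch == "EUR") 2.5e-5 else 0.78e-5
  t_ooa <- round(t_ooa_years / generation_time)
  t_split <- round(t_split_years / generation_time)
  t_af <- round(t_af_years / generation_time)
  sizes0 <- rep(n_af, t_af)              # African deme, generations 0..t_af-1
  gens1 <- 0:(t_ooa - 1)
  sizes1 <- ifelse(gens1 < t_split,
                   n_daughter0 * exp(growth * (t_split - gens1)), n_b)
  mig <- ifelse(gens1 < t_split, m_af_daughter, m_af_b)
  structure(list(branch = branch, generation_time = generation_time,
                 sizes0 = sizes0, anc_size = n_anc, sizes1 = sizes1,
                 mig = mig, t_ooa = t_ooa, t_split = t_split,
                 n_demes = 2L),
            class = "demography")
}

#' Single-deme constant-size demography
#'
#' Mainly for validating the simulator against closed-form neutral
#' expectations.
#'
#' @param n_e constant diploid effective size.
#' @param generation_time years per generation.
#' @return A `demography` object with one deme.
#' @export
constant_demography <- function(n_e, generation_time = 25) {
  structure(list(branch = "CONST", generation_time = generation_time,
                 sizes0 = n_e, anc_size = n_e,
                 sizes1 = numeric(0), mig = numeric(0), t_ooa = 0L,
                 t_split = 0L, n_demes = 1L),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("demography '%s': %d deme(s), generation time %g y\n",
              x$branch, x$n_demes, x$generation_time))
  invisible(x)
}
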