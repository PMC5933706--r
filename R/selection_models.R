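#' Selection model specification
#'
#' Identifies one of the candidate evolutionary models and its parameters:
#' selection on a de novo mutation (SDN), selection on standing variation
#' (SSV), neutrality (NTR), and the halted variants in which selection
#' ceases `halt_age` years ago. Selection coefficients are fractions
#' (0.01 = 1%); times are years before present; dominance is additive
#' (h = 0.5) throughout.
#'
#' @param model one of `"SDN"`, `"SSV"`, `"NTR"`, `"SDN_halted"`,
#'   `"SSV_halted"`.
#' @param t_sel years ago: allele birth (SDN/NTR) or selection onset (SSV).
#' @param s_A selection coefficient in Africa (SDN only).
#' @param s_NA selection coefficient in the non-African deme.
#' @param f_sel standing frequency at selection onset (SSV only).
#' @param halt_age years ago at which selection ceases (halted variants).
#' @return A `selection_model_spec` object.
#' @export
selection_model_spec <- function(model, t_sel, s_A = 0, s_NA = 0,
                                 f_sel = NA_real_, halt_age = 0) {
  model <- match.arg(model, c("SDN", "SSV", "NTR", "SDN_halted", "SSV_halted"))
  if (s_A < 0 || s_A > 0.05 || s_NA < 0 || s_NA > 0.05)
    stop("selection coefficients must lie in [0, 0.05]")
  if (grepl("SSV", model) && (is.na(f_sel) || f_sel <= 0 || f_sel > 0.2))
    stop("SSV requires f_sel in (0, 0.2]")
  structure(list(model = model, t_sel = t_sel, s_A = s_A, s_NA = s_NA,
                 f_sel = f_sel, halt_age = halt_age, h = 0.5),
            class = "selection_model_spec")
}

#' Draw a model specification from its prior
#'
#' Priors: SDN t_sel ~ U(30,000, 60,000) years ago, s_A ~ U(0, 1.5%),
#' s_NA ~ U(0.5%, 5%); SSV t_sel ~ U(21,000, 51,000) (between the
#' out-of-Africa migration and the European-Asian split), f_sel ~ U(0, 20%),
#' s_NA ~ U(0, 5%); NTR as SDN with all selection coefficients 0. Halted
#' variants use the same priors plus selection ceasing `halt_age` = 3,000
#' years ago.
#'
#' @param model model label as in [selection_model_spec()].
#' @return A `selection_model_spec` drawn from the prior (uses the current
#'   RNG state).
#' @export
sample_prior <- function(model) {
  model <- match.arg(model, c("SDN", "SSV", "NTR", "SDN_halted", "SSV_halted"))
  halted <- grepl("halted", model)
  base <- sub("_halted", "", model)
  spec <- switch(base,
    SDN = selection_model_spec(model, t_sel = stats::runif(1, 30000, 60000),
                               s_A = stats::runif(1, 0, 0.015),
                               s_NA = stats::runif(1, 0.005, 0.05),
                               halt_age = if (halted) 3000 else 0),
    SSV = selection_model_spec(model, t_sel = stats::runif(1, 21000, 51000),
                               s_NA = stats::runif(1, 0, 0.05),
                               f_sel = stats::runif(1, 1e-6, 0.2),
                               halt_age = if (halted) 3000 else 0),
    NTR = selection_model_spec("NTR", t_sel = stats::runif(1, 30000, 60000)))
  spec
}

#' Deterministic (infinite population) selection recursion
#'
#' One-deme logistic allele-frequency recursion under genotype fitnesses
#' 1, 1+hs, 1+s.
#'
#' @param p0 starting frequency.
#' @param s selection coefficient.
#' @param h dominance (default 0.5).
#' @param n_gen generations to iterate.
#' @return Numeric vector of length `n_gen + 1` (including `p0`).
#' @export
wf_deterministic <- function(p0, s, h = 0.5, n_gen) {
  p <- numeric(n_gen + 1)
  p[1] <- p0
  for (g in seq_len(n_gen)) {
    q <- p[g]
    wbar <- q^2 * (1 + s) + 2 * q * (1 - q) * (1 + h * s) + (1 - q)^2
    p[g + 1] <- (q^2 * (1 + s) + q * (1 - q) * (1 + h * s)) / wbar
  }
  p
}
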