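#' Simulate a derived-allele frequency trajectory
#'
#' Forward Wright-Fisher binomial trajectory under the model specification
#' and demography, with additive selection and migration. SDN/NTR alleles
#' are born as a single copy in the African deme at `t_sel`; SSV alleles
#' are at `f_sel` in both demes at onset, with the pre-onset neutral
#' history constructed backward from the onset frequency, conditioned on
#' loss into the past. Trajectories where the allele is lost before the
#' present are rejected and redrawn (counts reported).
#'
#' @param spec a [selection_model_spec()].
#' @param demography a [gravel_demography()] or [constant_demography()].
#' @param max_tries rejection budget before failing.
#' @param deterministic use the infinite-population recursion (no drift,
#'   no rejection) for the forward phase.
#' @return List with `x0`, `x1` (per-generation frequencies, index 1 =
#'   present), `g_birth`, `n_lost`, `n_fixed_back`.
#' @export
simulate_trajectory <- function(spec, demography, max_tries = 10000,
                                deterministic = FALSE) {
  stopifnot(inherits(spec, "selection_model_spec"),
            inherits(demography, "demography"))
  gt <- demography$generation_time
  g_start <- round(spec$t_sel / gt)
  halt_gen <- round(spec$halt_age / gt)
  model_code <- if (grepl("SSV", spec$model)) 1L else 0L
  out <- simulate_trajectory_cpp(
    model_code, g_start, spec$s_A, spec$s_NA,
    if (is.na(spec$f_sel)) 0 else spec$f_sel, halt_gen,
    demography$sizes0, demography$anc_size, demography$sizes1,
    demography$mig, demography$t_ooa, max_tries, deterministic)
  if (!is.null(out$failed))
    stop(sprintf("allele lost in all %d trajectory attempts", max_tries))
  out
}

#' Replace recombination hotspots by extended baseline-rate stretches
#'
#' Intervals with recombination rate above `threshold` (cM/Mb) are treated
#' as hotspots: each hotspot of physical length l and rate rho_h is
#' replaced by a stretch of length l * rho_h / rho_0 at the baseline rate
#' rho_0 (the bp-weighted mean rate across the locus excluding the
#' hotspots), conserving total genetic length. The inserted excess
#' contributes recombination but is masked for mutations; surviving
#' coordinates are projected back onto the original frame.
#'
#' @param map a [genetic_map()] covering `[1, L]`.
#' @param L locus length (bp) in original coordinates.
#' @param threshold hotspot definition (cM/Mb), default 5.
#' @return A `hotspot_extension` list: `L_ext`, `rate0` (cM/Mb), `mask`
#'   (matrix of masked [start,end) intervals in extended coordinates),
#'   `pieces` (projection table), and helpers `to_original(pos)` /
#'   `to_extended(pos)`.
#' @export
apply_hotspot_extension <- function(map, L, threshold = 5) {
  stopifnot(inherits(map, "genetic_map"))
  brk <- unique(c(1, map$pos[map$pos > 1 & map$pos < L], L))
  brk <- sort(brk)
  starts <- brk[-length(brk)]
  ends <- brk[-1]
  rate <- map$rate[pmax(findInterval(starts, map$pos), 1L)]
  hot <- rate > threshold
  if (all(hot)) stop("baseline rate undefined: the whole locus is hotspot")
  rate0 <- sum(rate[!hot] * (ends - starts)[!hot]) / sum((ends - starts)[!hot])
  if (rate0 == 0 && any(hot))
    stop("baseline rate 0 with hotspots present")
  # extended layout: hotspot pieces inflate by rate/rate0; the first
  # (original-length) part of each inflated piece projects back, the rest
  # is masked
  phys_len <- ends - starts
  ext_len <- ifelse(hot, phys_len * rate / rate0, phys_len)
  ext_start <- cumsum(c(1, ext_len[-length(ext_len)]))
  mask <- cbind(start = ext_start[hot] + phys_len[hot],
                end = ext_start[hot] + ext_len[hot])
  pieces <- data.frame(orig_start = starts, phys_len = phys_len,
                       ext_start = ext_start, ext_len = ext_len, hot = hot)
  L_ext <- ext_start[length(ext_start)] + ext_len[length(ext_len)]
  to_original <- function(pos) {
    i <- pmax(findInterval(pos, pieces$ext_start), 1L)
    off <- pos - pieces$ext_start[i]
    out <- pieces$orig_start[i] + off
    out[off >= pieces$phys_len[i]] <- NA_real_  # masked excess
    out
  }
  to_extended <- function(pos) {
    i <- pmax(findInterval(pos, pieces$orig_start), 1L)
    pieces$ext_start[i] + (pos - pieces$orig_start[i])
  }
  structure(list(L_ext = L_ext, rate0 = rate0, mask = mask, pieces = pieces,
                 to_original = to_original, to_extended = to_extended,
                 threshold = threshold, map = map),
            class = "hotspot_extension")
}

#' Simulate a two-deme locus under a selection model
#'
#' Runs the trajectory-conditioned structured coalescent for a locus of
#' length `L`: lineages are partitioned into focal-allele classes whose
#' sizes follow the simulated trajectory; recombination moves lineages
#' between classes; neutral variation accumulates along the resulting
#' genealogies. Recombination hotspots in `map` are handled by the
#' extension construction of [apply_hotspot_extension()]. With `spec =
#' NULL` the locus is simulated as fully neutral and unconditioned (no
#' focal site), which is the configuration used to check the simulator
#' against closed-form coalescent expectations.
#'
#' @param spec a [selection_model_spec()] or `NULL`.
#' @param demography a `demography` object.
#' @param map a [genetic_map()] or `NULL` for a uniform 1.2 cM/Mb map.
#' @param L locus length in bp (default 185,000).
#' @param n_hap haplotypes sampled per deme, `c(African, non-African)`.
#' @param mu mutation rate per bp per generation.
#' @param focal_position physical position of the selected site (default:
#'   midpoint of the central 65 kb section).
#' @param max_tries trajectory rejection budget.
#' @return List with `hm` (a [haplotype_matrix()], populations `"AFR"` and
#'   `"NONAFR"`), `focal_position` (`NA` for unconditioned runs),
#'   `trajectory`, `spec`, `n_lost` (trajectory rejections).
#' @export
simulate_locus <- function(spec, demography, map = NULL, L = 185000,
                           n_hap = c(122, 122), mu = 1.25e-8,
                           focal_position = NULL, max_tries = 10000,
                           min_test_daf = NULL) {
  if (is.null(map)) map <- genetic_map(c(1, L), c(1.2, 1.2))
  ext <- apply_hotspot_extension(map, L)
  r_bp <- ext$rate0 * 1e-8  # cM/Mb -> Morgans per bp
  if (is.null(focal_position)) focal_position <- round(L / 2)
  focal_ext <- ext$to_extended(focal_position)
  n0 <- n_hap[1]
  n1 <- if (demography$n_demes > 1) n_hap[2] else 0
  if (n0 %% 2 != 0 || n1 %% 2 != 0)
    stop("n_hap must be even per deme (two haplotypes per diploid)")

  conditioned <- !is.null(spec)
  if (conditioned) {
    traj <- simulate_trajectory(spec, demography, max_tries)
    nder0 <- stats::rbinom(1, n0, traj$x0[1])
    nder1 <- if (n1 > 0) stats::rbinom(1, n1, traj$x1[1]) else 0L
    # the XP-EHH computability filter depends only on the sampled focal
    # counts, so apply it before the (expensive) coalescent
    if (!is.null(min_test_daf) && n1 > 0 && nder1 / n1 <= min_test_daf)
      return(list(hm = NULL, excluded = TRUE, trajectory = traj,
                  spec = spec, n_lost = traj$n_lost))
    x0 <- traj$x0; x1 <- traj$x1; g_birth <- traj$g_birth
  } else {
    traj <- NULL
    nder0 <- 0L; nder1 <- 0L; x0 <- 0; x1 <- 0; g_birth <- -1L
  }

  raw <- sim_locus_cpp(x0, x1, g_birth, n0, n1, nder0, nder1,
                       demography$sizes0, demography$anc_size,
                       demography$sizes1, demography$mig,
                       demography$t_ooa, ext$L_ext, r_bp, mu,
                       focal_ext, conditioned)
  pos <- ext$to_original(raw$pos)
  ok <- !is.na(pos)
  pos <- round(pos[ok])
  geno <- raw$geno[, ok, drop = FALSE]
  # infinite-sites positions are continuous; resolve integer collisions and
  # keep the focal position free
  keep <- !duplicated(pos) & pos != focal_position & pos >= 1 & pos <= L
  pos <- pos[keep]; geno <- geno[, keep, drop = FALSE]
  if (conditioned) {
    focal_col <- as.integer(c(seq_len(n0) <= nder0,
                              seq_len(n1) <= nder1))
    geno <- cbind(geno, focal_col)
    pos <- c(pos, focal_position)
  }
  ord <- order(pos)
  pops <- c(rep("AFR", n0), rep("NONAFR", n1))
  ids <- paste0(pops, "_ind", formatC(ceiling(seq_len(n0 + n1) / 2),
                                      width = 3, flag = "0"))
  hm <- haplotype_matrix(geno[, ord, drop = FALSE], pos[ord], ids, pops)
  list(hm = hm, focal_position = if (conditioned) focal_position else NA,
       trajectory = traj, spec = spec, excluded = FALSE,
       n_lost = if (conditioned) traj$n_lost else 0L)
}
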