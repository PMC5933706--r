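#' The 14-statistic ABC summary vector for a two-deme locus
#'
#' Statistics: XP-EHH at the focal site (non-African test vs African
#' reference, whole region); Tajima's D and Fay & Wu's H per deme for the
#' central section and the combined flanks (8 values); mean per-site F_ST
#' between the demes per section (2); derived allele frequency at the focal
#' site in each deme (2); and per-site F_ST at the focal site. Records
#' where the focal derived allele frequency in the test (non-African) deme
#' is at or below 5% are flagged excluded (the XP-EHH computability filter),
#' as are records with any undefined statistic.
#'
#' @param hm a [haplotype_matrix()] with populations `"AFR"` and `"NONAFR"`.
#' @param focal_position physical position of the focal site.
#' @param map a [genetic_map()] for the EHH integration.
#' @param central `c(start, end)` of the central section (bp); the flanks
#'   are everything else. Default: the central 65 kb of a 185 kb frame.
#' @param min_test_daf exclusion threshold on the test-deme focal DAF.
#' @return List with `stats` (named numeric, length 14), `excluded`
#'   (logical), `reason`.
#' @export
compute_sumstat_vector <- function(hm, focal_position, map,
                                   central = c(60000, 125000),
                                   min_test_daf = 0.05) {
  pops <- unique(hm$population)
  if (!all(c("AFR", "NONAFR") %in% pops)) stop("need demes AFR and NONAFR")
  rows_afr <- which(hm$population == "AFR")
  rows_na <- which(hm$population == "NONAFR")
  j0 <- site_index(hm, focal_position)

  daf_afr <- mean(hm$alleles[rows_afr, j0])
  daf_na <- mean(hm$alleles[rows_na, j0])
  if (daf_na <= min_test_daf)
    return(list(stats = NULL, excluded = TRUE, reason = "test DAF <= 5%"))

  in_central <- hm$positions >= central[1] & hm$positions <= central[2]
  sections <- list(central = which(in_central), flanks = which(!in_central))

  deme_rows <- list(AFR = rows_afr, NONAFR = rows_na)
  stats <- c(xpehh_core = xpehh_site(hm_subset(hm, rows_na),
                                     hm_subset(hm, rows_afr),
                                     focal_position, map))
  for (dm in names(deme_rows)) for (sec in names(sections)) {
    rows <- deme_rows[[dm]]; sites <- sections[[sec]]
    n <- length(rows)
    sfs <- sfs_from_matrix(hm, rows, sites)
    stats[paste0("tajd_", tolower(dm), "_", sec)] <-
      tajimas_d_matrix(hm, rows, sites)
    stats[paste0("fwh_", tolower(dm), "_", sec)] <- fay_wu_h(sfs, n)
  }
  n1 <- length(rows_afr) / 2; n2 <- length(rows_na) / 2
  for (sec in names(sections)) {
    sites <- sections[[sec]]
    p1 <- colMeans(hm$alleles[rows_afr, sites, drop = FALSE])
    p2 <- colMeans(hm$alleles[rows_na, sites, drop = FALSE])
    poly <- p1 + p2 > 0 & p1 + p2 < 2
    comp <- wc_components_pair(p1[poly], p2[poly], n1, n2)
    theta <- comp$a / comp$total
    stats[paste0("fst_", sec)] <- mean(theta[is.finite(theta)])
  }
  stats["daf_afr"] <- daf_afr
  stats["daf_nonafr"] <- daf_na
  comp0 <- wc_components_pair(daf_afr, daf_na, n1, n2)
  stats["fst_focal"] <- comp0$a / comp0$total
  if (any(!is.finite(stats)))
    return(list(stats = stats, excluded = TRUE,
                reason = "undefined statistic"))
  list(stats = stats, excluded = FALSE, reason = NA_character_)
}

#' Build an ABC reference table for one model
#'
#' Draws parameters from the model prior, simulates the locus, and computes
#' the summary vector, keeping track of excluded records so the realized
#' (filtered) prior is known.
#'
#' @param model model label (see [selection_model_spec()]).
#' @param n_sims number of retained (non-excluded) simulations requested.
#' @param demography,map,L,n_hap,mu,focal_position passed to
#'   [simulate_locus()].
#' @param max_draws cap on total prior draws (default `20 * n_sims`).
#' @param verbose print progress every 500 simulations.
#' @return data.frame with columns model, t_sel, s_A, s_NA, f_sel and the
#'   14 statistics; attributes `n_drawn` and `n_excluded`.
#' @export
build_reference_table <- function(model, n_sims, demography, map = NULL,
                                  L = 185000, n_hap = c(122, 122),
                                  mu = 1.25e-8, focal_position = NULL,
                                  max_draws = 20 * n_sims, verbose = FALSE) {
  if (is.null(focal_position)) focal_position <- round(L / 2)
  if (is.null(map)) map <- genetic_map(c(1, L), c(1.2, 1.2))
  rows <- vector("list", n_sims)
  kept <- 0L; drawn <- 0L; excluded <- 0L
  while (kept < n_sims && drawn < max_draws) {
    drawn <- drawn + 1L
    spec <- sample_prior(model)
    sim <- simulate_locus(spec, demography, map, L, n_hap, mu, focal_position,
                          min_test_daf = 0.05)
    if (isTRUE(sim$excluded)) { excluded <- excluded + 1L; next }
    sv <- compute_sumstat_vector(sim$hm, focal_position, map)
    if (sv$excluded) { excluded <- excluded + 1L; next }
    kept <- kept + 1L
    rows[[kept]] <- data.frame(model = model, t_sel = spec$t_sel,
                               s_A = spec$s_A, s_NA = spec$s_NA,
                               f_sel = ifelse(is.na(spec$f_sel), 0,
                                              spec$f_sel),
                               t(sv$stats), stringsAsFactors = FALSE)
    if (verbose && kept %% 500 == 0)
      message(sprintf("%s: %d / %d", model, kept, n_sims))
  }
  if (kept < n_sims)
    warning(sprintf("%s: only %d of %d simulations kept within draw budget",
                    model, kept, n_sims))
  out <- do.call(rbind, rows[seq_len(kept)])
  attr(out, "n_drawn") <- drawn
  attr(out, "n_excluded") <- excluded
  out
}

#' Names of the summary-statistic columns in a reference table
#' @param ref a reference table.
#' @return Character vector of statistic column names.
#' @export
sumstat_columns <- function(ref)
  setdiff(colnames(ref), c("model", "t_sel", "s_A", "s_NA", "f_sel"))

# Box-Cox profile-likelihood lambda for a positive vector
boxcox_lambda <- function(x) {
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-3, 3, 0.05), plotit = FALSE)
  bc$x[which.max(bc$y)]
}

boxcox_apply <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Fit the Box-Cox + PLS summary-statistic transform
#'
#' Each statistic is shifted positive, Box-Cox transformed with a
#' profile-ML lambda, and standardized; a PLS regression of the model
#' parameters on the transformed statistics (pooled across models, with
#' absent parameters coded 0) supplies the low-dimensional projection used
#' for the rejection distance. Constant statistics are dropped with a
#' warning.
#'
#' @param ref pooled reference table ([build_reference_table()] rows from
#'   all models).
#' @param n_components number of PLS components to keep (default 5).
#' @return A `boxcox_pls_transform` object.
#' @export
fit_transform <- function(ref, n_components = 5) {
  stat_cols <- sumstat_columns(ref)
  X <- as.matrix(ref[, stat_cols, drop = FALSE])
  if (nrow(X) < 100) stop("need at least 100 reference rows")
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep))
    warning(sprintf("dropping constant statistic(s): %s",
                    paste(stat_cols[!keep], collapse = ", ")))
  X <- X[, keep, drop = FALSE]
  stat_cols <- stat_cols[keep]
  if (length(stat_cols) < n_components)
    stop("fewer statistics than PLS components")
  shift <- 1 - apply(X, 2, min)
  lambda <- numeric(ncol(X))
  Xt <- X
  for (j in seq_len(ncol(X))) {
    xp <- X[, j] + shift[j]
    lambda[j] <- boxcox_lambda(xp)
    Xt[, j] <- boxcox_apply(xp, lambda[j])
  }
  center <- colMeans(Xt)
  scale <- apply(Xt, 2, stats::sd)
  Xs <- sweep(sweep(Xt, 2, center), 2, scale, "/")
  Y <- as.matrix(ref[, c("t_sel", "s_A", "s_NA", "f_sel")])
  Y <- Y[, apply(Y, 2, stats::sd) > 0, drop = FALSE]  # drop absent params
  pls <- mixOmics::pls(Xs, Y, ncomp = n_components, mode = "regression",
                       scale = TRUE)
  structure(list(stat_cols = stat_cols, shift = shift, lambda = lambda,
                 center = center, scale = scale, pls = pls,
                 n_components = n_components),
            class = "boxcox_pls_transform")
}

#' Project summary statistics into the fitted PLS space
#'
#' @param transform a [fit_transform()] object.
#' @param stats a named numeric vector, a matrix, or a reference table.
#' @return Matrix (rows = observations, cols = PLS components).
#' @export
project_stats <- function(transform, stats) {
  tr <- transform
  if (is.data.frame(stats)) stats <- as.matrix(stats[, tr$stat_cols])
  if (is.null(dim(stats))) stats <- matrix(stats[tr$stat_cols], nrow = 1,
                                           dimnames = list(NULL, tr$stat_cols))
  stats <- stats[, tr$stat_cols, drop = FALSE]
  Xt <- stats
  for (j in seq_along(tr$stat_cols)) {
    xp <- pmax(stats[, j] + tr$shift[j], 1e-12)
    Xt[, j] <- boxcox_apply(xp, tr$lambda[j])
  }
  Xs <- sweep(sweep(Xt, 2, tr$center), 2, tr$scale, "/")
  pr <- stats::predict(tr$pls, Xs)
  pr$variates[, seq_len(tr$n_components), drop = FALSE]
}

#' Held-out RMSE of parameter prediction per PLS component count
#'
#' Linear prediction of each parameter from the first c components on a
#' held-out split, for c = 1..max_components; used to justify the number of
#' retained components.
#'
#' @param ref pooled reference table.
#' @param max_components largest component count examined.
#' @param holdout fraction of rows held out (default 0.25).
#' @return Matrix (max_components x parameters) of held-out RMSE.
#' @export
rmse_per_component <- function(ref, max_components = 8, holdout = 0.25) {
  n <- nrow(ref)
  test <- seq_len(n) %in% sample.int(n, round(holdout * n))
  tr <- fit_transform(ref[!test, , drop = FALSE],
                      n_components = max_components)
  Ztr <- project_stats(tr, ref[!test, , drop = FALSE])
  Zte <- project_stats(tr, ref[test, , drop = FALSE])
  pars <- c("t_sel", "s_A", "s_NA", "f_sel")
  out <- matrix(NA_real_, max_components, length(pars),
                dimnames = list(NULL, pars))
  for (p in pars) {
    ytr <- ref[[p]][!test]; yte <- ref[[p]][test]
    for (cc in seq_len(max_components)) {
      fit <- stats::lm.fit(cbind(1, Ztr[, seq_len(cc), drop = FALSE]), ytr)
      pred <- cbind(1, Zte[, seq_len(cc), drop = FALSE]) %*% fit$coefficients
      out[cc, p] <- sqrt(mean((yte - pred)^2))
    }
  }
  out
}

#' ABC rejection step
#'
#' Euclidean nearest neighbours of the observation in PLS space across the
#' pooled reference table; ties broken by simulation index.
#'
#' @param observed named statistic vector (as from
#'   [compute_sumstat_vector()]`$stats`).
#' @param ref pooled reference table.
#' @param transform a [fit_transform()] object.
#' @param n_retain number of simulations to retain (default 1000).
#' @return The retained subset of `ref` with a `distance` column, ordered
#'   by distance.
#' @export
abc_reject <- function(observed, ref, transform, n_retain = 1000) {
  if (n_retain > nrow(ref)) stop("reference table smaller than n_retain")
  Z <- project_stats(transform, ref)
  z0 <- project_stats(transform, observed)
  d <- sqrt(rowSums(sweep(Z, 2, as.numeric(z0))^2))
  ord <- order(d, seq_along(d))[seq_len(n_retain)]
  out <- ref[ord, , drop = FALSE]
  out$distance <- d[ord]
  out
}

#' Posterior model probabilities and Bayes factor from a retained set
#'
#' Retained counts per model are divided by the number of simulations of
#' that model in the reference table (correcting unequal simulation
#' effort), then normalized: equal prior model probabilities. The Bayes
#' factor is the posterior odds of the best model,
#' BF = PP / (1 - PP).
#'
#' @param retained result of [abc_reject()] (needs a `model` column).
#' @param simulated_counts named vector: simulations per model in the
#'   reference table.
#' @return List with `posterior` (named, sums to 1), `best`,
#'   `bayes_factor`.
#' @export
model_posterior <- function(retained, simulated_counts) {
  models <- names(simulated_counts)
  if (any(simulated_counts <= 0)) stop("every model needs > 0 simulations")
  cnt <- vapply(models, function(m) sum(retained$model == m), numeric(1))
  pp <- (cnt / simulated_counts)
  pp <- pp / sum(pp)
  best <- models[which.max(pp)]
  ppb <- pp[best]
  bf <- if (ppb >= 1) Inf else ppb / (1 - ppb)
  list(posterior = pp, best = best, bayes_factor = unname(bf))
}

#' Convert between a Bayes factor and the posterior probability it implies
#'
#' Under the identity BF = PP / (1 - PP).
#'
#' @param bf Bayes factor(s).
#' @return Posterior probability of the favoured model.
#' @export
bayes_factor_to_posterior <- function(bf) bf / (1 + bf)

#' Posterior parameter summaries from a retained set
#'
#' Unweighted rejection-posterior quantiles of the retained parameter
#' values for one model.
#'
#' @param retained result of [abc_reject()].
#' @param model model whose retained rows are summarized.
#' @param params parameter columns to summarize.
#' @return data.frame with parameter, median, q025, q975 and attribute
#'   `low_confidence` (TRUE when < 20 retained rows).
#' @export
parameter_posterior <- function(retained, model,
                                params = c("t_sel", "s_NA", "f_sel")) {
  rows <- retained[retained$model == model, , drop = FALSE]
  out <- do.call(rbind, lapply(params, function(p) {
    q <- stats::quantile(rows[[p]], c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, median = q[2], q025 = q[1], q975 = q[3])
  }))
  attr(out, "low_confidence") <- nrow(rows) < 20
  attr(out, "n_retained") <- nrow(rows)
  out
}

#' Cross-validation power of the ABC model choice
#'
#' Draws pseudo-observations from the reference tables, scores each against
#' the remaining reference (the pseudo-observation's own row is excluded),
#' and assigns it to the model with the highest posterior probability.
#'
#' @param ref pooled reference table.
#' @param n_pseudo pseudo-observations per model.
#' @param accept_frac acceptance fraction defining the retained set size
#'   (default 0.001, i.e. top 0.1%).
#' @param transform optional pre-fitted [fit_transform()]; fitted on `ref`
#'   when `NULL`.
#' @param models model subset to cross-validate (default: all in `ref`).
#' @return List with `confusion` (counts matrix true x assigned),
#'   `fraction_correct` (named), `tp_fp_fn` (data.frame).
#' @export
cross_validation_power <- function(ref, n_pseudo = 200, accept_frac = 0.001,
                                   transform = NULL, models = NULL) {
  if (is.null(models)) models <- unique(ref$model)
  ref <- ref[ref$model %in% models, , drop = FALSE]
  if (is.null(transform)) transform <- fit_transform(ref)
  Z <- project_stats(transform, ref)
  sim_counts <- table(ref$model)[models]
  n_retain <- max(1L, round(accept_frac * nrow(ref)))
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(true = models, assigned = models))
  for (m in models) {
    idx_m <- which(ref$model == m)
    picks <- sample(idx_m, min(n_pseudo, length(idx_m)))
    for (i in picks) {
      d <- sqrt(rowSums(sweep(Z, 2, Z[i, ])^2))
      d[i] <- Inf  # exclude the pseudo-observation itself
      ord <- order(d, seq_along(d))[seq_len(n_retain)]
      cnt <- vapply(models, function(mm) sum(ref$model[ord] == mm),
                    numeric(1))
      cnt_adj <- cnt / as.numeric(sim_counts)
      assigned <- models[which.max(cnt_adj)]
      confusion[m, assigned] <- confusion[m, assigned] + 1L
    }
  }
  frac <- diag(confusion) / rowSums(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  list(confusion = confusion,
       fraction_correct = stats::setNames(frac, models),
       tp_fp_fn = data.frame(model = models, TP = tp, FP = fp, FN = fn,
                             row.names = NULL))
}

#' Model choice including the halted-selection variants
#'
#' Runs the rejection model choice over the halted model set (halted SDN,
#' halted SSV, NTR) and over the full five-model set, with the same
#' machinery.
#'
#' @param ref pooled reference table that must contain `SDN_halted` and
#'   `SSV_halted` rows alongside SDN, SSV and NTR.
#' @param observed named statistic vector.
#' @param n_retain retained simulations per comparison.
#' @return List with `halted` and `all_models` [model_posterior()] results.
#' @export
run_halted_comparison <- function(ref, observed, n_retain = 1000) {
  need <- c("SDN_halted", "SSV_halted")
  if (!all(need %in% ref$model))
    stop("halted reference tables absent")
  halted_set <- c("SDN_halted", "SSV_halted", "NTR")
  all_set <- c("SDN", "SSV", "NTR", "SDN_halted", "SSV_halted")
  run_one <- function(models) {
    sub <- ref[ref$model %in% models, , drop = FALSE]
    tr <- fit_transform(sub)
    ret <- abc_reject(observed, sub, tr, min(n_retain, nrow(sub)))
    model_posterior(ret, table(sub$model)[models])
  }
  list(halted = run_one(halted_set), all_models = run_one(all_set))
}
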