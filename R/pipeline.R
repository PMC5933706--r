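#' Per-population selection-scan report
#'
#' One row per population: derived allele frequency at the focal SNP, F_ST
#' to the reference population (computed from allele counts with HWE
#' heterozygosity), its empirical P-value against the background SNP
#' distribution, and placeholders following the scan's NA conventions: the
#' reference population's F_ST against itself is not reported, and iHS is
#' not reported for populations whose focal DAF falls outside the
#' scan's frequency bounds.
#'
#' @param records genotype records (see [read_genotype_table()]).
#' @param meta population metadata (one row per population).
#' @param background result of [generate_background()] (or a compatible
#'   list with `counts` per population) supplying the empirical F_ST null;
#'   `NULL` skips empirical P-values.
#' @param reference_pop label of the reference population.
#' @param maf_bounds iHS eligibility bounds on the focal DAF.
#' @return data.frame: population, latitude, temperature, n, daf, fst,
#'   fst_pvalue, ihs_eligible, note.
#' @export
run_scan <- function(records, meta, background = NULL,
                     reference_pop, maf_bounds = c(0.05, 0.95)) {
  recs <- records[!isTRUE(records$missing) & !is.na(records$derived_count), ]
  pops <- meta$population
  if (!reference_pop %in% pops) stop("reference population absent from meta")
  per_pop <- function(p) {
    r <- recs[recs$population == p, ]
    c(n = nrow(r), der = sum(r$derived_count))
  }
  tab <- vapply(pops, per_pop, numeric(2))
  daf <- tab["der", ] / (2 * tab["n", ])
  ref <- which(pops == reference_pop)

  fst <- rep(NA_real_, length(pops))
  fst_p <- rep(NA_real_, length(pops))
  if (!is.null(background)) {
    n_bg <- attr(background, "n_individuals")
    if (is.null(n_bg)) n_bg <- max(tab["n", ])
  }
  for (i in seq_along(pops)) {
    if (i == ref) next
    sc <- site_counts(n = tab["n", c(i, ref)],
                      derived_count = tab["der", c(i, ref)])
    fst[i] <- wc_fst_site(sc)$theta
    if (!is.null(background)) {
      p_i <- background$counts[pops[i], ] / (2 * n_bg)
      p_r <- background$counts[reference_pop, ] / (2 * n_bg)
      comp <- wc_components_pair(p_i, p_r, n_bg, n_bg)
      theta_bg <- comp$a / comp$total
      theta_bg <- theta_bg[is.finite(theta_bg)]
      fst_p[i] <- empirical_pvalue(fst[i], theta_bg, "upper")
    }
  }
  note <- rep("", length(pops))
  note[ref] <- "reference population: F_ST not calculated"
  ihs_ok <- daf > maf_bounds[1] & daf < maf_bounds[2]
  note[!ihs_ok & note == ""] <- "focal DAF outside iHS frequency bounds"
  data.frame(population = pops, latitude = meta$latitude,
             temperature = meta$temperature, n = tab["n", ], daf = daf,
             fst = fst, fst_pvalue = fst_p, ihs_eligible = ihs_ok,
             note = note, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cline model comparison report (PGLS or GLMM)
#'
#' Fits the null model and every model that can be built from the test
#' predictors, and returns the AIC multi-model comparison. For PGLS the
#' response is the per-population mean derived allele frequency and shared
#' ancestry enters through the midpoint-rooted NJ tree of the pairwise
#' F_ST matrix (AICc is used). For the GLMM the response is the
#' two-column allele-count matrix per individual and shared ancestry enters
#' as the F_ST-to-reference fixed effect plus a population random effect
#' (plain AIC).
#'
#' @param records genotype records.
#' @param meta population metadata.
#' @param fst_matrix pairwise genome-wide F_ST matrix (row/col names =
#'   populations).
#' @param method `"pgls"` or `"glmm"`.
#' @param predictors test predictor columns (subset of names in
#'   `meta`/`records`).
#' @param reference_pop reference population for the GLMM F_ST covariate.
#' @return List with `fits`, `table` (the [multimodel_table()]), `lrt`
#'   (null vs full comparison), and `tree` for PGLS.
#' @export
run_cline <- function(records, meta, fst_matrix,
                      method = c("pgls", "glmm"),
                      predictors = c("latitude", "temperature"),
                      reference_pop = NULL) {
  method <- match.arg(method)
  subsets <- unlist(lapply(0:length(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  label_of <- function(s) if (length(s)) paste(c("Null", s), collapse = "+")
    else "Null"

  if (method == "pgls") {
    tree <- midpoint_root(fst_nj_tree(fst_matrix))
    recs <- records[!is.na(records$derived_count), ]
    daf <- tapply(recs$derived_count, recs$population, mean) / 2
    data <- meta
    data$daf <- as.numeric(daf[data$population])
    for (p in predictors) data[[paste0("z_", p)]] <- z_transform(data[[p]])
    fits <- lapply(subsets, function(s) {
      rhs <- if (length(s)) paste(paste0("z_", s), collapse = " + ") else "1"
      f <- stats::as.formula(paste("daf ~", rhs))
      # parameter bookkeeping: intercept + slopes + variance, plus the
      # tree-scaling convention used by published comparison tables
      pgls_fit(f, data, tree, k = length(s) + 4, label = label_of(s))
    })
    tab <- multimodel_table(fits, use_aicc = TRUE)
    l <- lrt(fits[[1]], fits[[length(fits)]])
    return(list(fits = fits, table = tab, lrt = l, tree = tree))
  }

  if (is.null(reference_pop)) stop("glmm needs a reference population")
  fst_ref <- fst_matrix[, reference_pop]
  fits <- lapply(subsets, function(s)
    glmm_fit(records, fixed = s, fst_to_reference = fst_ref,
             label = label_of(s)))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab <- multimodel_table(fits[ok])
  l <- if (ok[1] && ok[length(fits)])
    lrt(fits[[1]], fits[[length(fits)]]) else NULL
  list(fits = fits, table = tab, lrt = l)
}

#' ABC report for one observed dataset
#'
#' Rejection ABC against a pooled reference table: model posterior
#' probabilities, Bayes factor, and parameter posterior for the winning (or
#' a requested) model.
#'
#' @param observed named statistic vector
#'   ([compute_sumstat_vector()]`$stats`).
#' @param ref pooled reference table.
#' @param n_retain retained simulations (default: 0.1% of the table, at
#'   least 100).
#' @param transform optional pre-fitted transform.
#' @param report_model model whose parameters are summarized (default: the
#'   best model).
#' @return List with `model_choice`, `parameters`, `n_retain`.
#' @export
run_abc <- function(observed, ref, n_retain = NULL, transform = NULL,
                    report_model = NULL) {
  if (is.null(n_retain)) n_retain <- max(100L, round(0.001 * nrow(ref)))
  if (is.null(transform)) transform <- fit_transform(ref)
  ret <- abc_reject(observed, ref, transform, n_retain)
  mc <- model_posterior(ret, table(ref$model)[unique(ref$model)])
  if (is.null(report_model)) report_model <- mc$best
  pp <- parameter_posterior(ret, report_model)
  list(model_choice = mc, parameters = pp, n_retain = n_retain,
       retained = ret)
}
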