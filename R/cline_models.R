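#' z-transform a predictor
#'
#' Centers to mean 0 and scales to sd 1 (n-1 denominator).
#'
#' @param values numeric vector with at least two distinct values.
#' @return Standardized vector.
#' @export
z_transform <- function(values) {
  if (length(unique(values)) < 2) stop("constant input cannot be z-transformed")
  (values - mean(values)) / stats::sd(values)
}

#' Neighbor-joining population tree from a pairwise F_ST matrix
#'
#' Saitou-Nei neighbor joining on the distance matrix; negative inferred
#' branch lengths are clamped to zero with the deficit moved to the sister
#' branch, preserving leaf-to-leaf path lengths where possible.
#'
#' @param d symmetric non-negative distance matrix with population row
#'   names.
#' @return An [ape::nj()] `phylo` tree (unrooted).
#' @export
fst_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  tree <- ape::nj(d)
  # clamp negative branches, moving the deficit to the sister branch
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sib)) tree$edge.length[sib[1]] <-
        tree$edge.length[sib[1]] + deficit
  }
  tree
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree a `phylo` tree.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) == 2) {
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, length(tree$edge.length))
    tree$root.edge <- 0
    return(tree)
  }
  phangorn::midpoint(tree)
}

#' Phylogenetic generalized least squares under Brownian covariance
#'
#' GLS with residual covariance proportional to the Brownian-motion matrix
#' C of the tree (C_ij = shared root-to-MRCA path length), with Pagel's
#' lambda scaling the off-diagonal elements. Coefficients are the GLS
#' estimator (X' V^-1 X)^-1 X' V^-1 y; sigma^2 is the ML estimate, and the
#' log-likelihood is that of the Gaussian GLS model, so nested fits can be
#' compared by likelihood ratio. AICc applies the small-sample correction
#' 2k(k+1)/(n-k-1).
#'
#' @param formula model formula; variables are looked up in `data`.
#' @param data data.frame with one row per population; row names (or a
#'   `population` column) must match the tree's tip labels.
#' @param tree rooted `phylo` tree whose tips are the populations.
#' @param lambda Pagel's lambda multiplying off-diagonal covariance
#'   (default 1, full Brownian structure; 0 gives independent residuals).
#' @param k parameter count used for AIC; defaults to the number of
#'   coefficients + 1 (the residual variance). Published tables sometimes
#'   use a different bookkeeping convention, so this is overridable.
#' @param label model label carried into comparison tables.
#' @return A `regression_fit` list: coefficients, log_likelihood, k, aic,
#'   aicc, sigma2, n, fitted, residuals.
#' @export
pgls_fit <- function(formula, data, tree, lambda = 1, k = NULL,
                     label = deparse(formula)) {
  if (!is.null(data$population)) rownames(data) <- data$population
  if (!all(tree$tip.label %in% rownames(data)))
    stop("tree tips and data rows must match")
  data <- data[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  V <- C
  off <- row(V) != col(V)
  V[off] <- lambda * V[off]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  Vi <- solve(V)
  if (!all(is.finite(Vi))) stop("singular phylogenetic covariance matrix")
  XtVi <- t(X) %*% Vi
  # qr.coef marks aliased (e.g. constant-zero) predictors NA, like lm
  beta <- qr.coef(qr(XtVi %*% X), XtVi %*% y)
  beta_filled <- ifelse(is.na(beta), 0, beta)
  resid <- y - X %*% beta_filled
  sigma2 <- as.numeric(t(resid) %*% Vi %*% resid) / n  # ML estimate
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                  determinant(V, logarithm = TRUE)$modulus + n)
  ll <- as.numeric(ll)
  if (is.null(k)) k <- ncol(X) + 1
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  structure(list(label = label, coefficients = stats::setNames(
    as.numeric(beta), colnames(X)), log_likelihood = ll, k = k, aic = aic,
    aicc = aicc, sigma2 = sigma2, n = n,
    fitted = as.numeric(X %*% beta), residuals = as.numeric(resid),
    converged = TRUE, method = "pgls"), class = "regression_fit")
}

#' Binomial mixed-model allele-frequency cline
#'
#' Logit-link binomial GLMM on a two-column response (derived and ancestral
#' allele counts per individual), with a population random intercept for
#' drift and an individual-level random intercept absorbing the
#' non-independence of the two allele counts (and overdispersion). Shared
#' ancestry is controlled by a fixed effect of each population's
#' genome-wide F_ST to the reference population. All fixed-effect
#' predictors are z-transformed before fitting. Fitted by Laplace-
#' approximated ML (lme4), so AICs are comparable across fixed-effect
#' structures. With a single population the model degenerates to a plain
#' binomial GLM (random-effect variances fixed at zero).
#'
#' @param records genotype records data.frame ([read_genotype_table()]
#'   layout); rows flagged `missing` are dropped.
#' @param fixed character vector of fixed-effect column names (e.g.
#'   `c("latitude", "temperature")`, optionally `"age_years"`).
#' @param fst_to_reference optional named vector of per-population
#'   genome-wide F_ST to the reference; included as a fixed effect when
#'   supplied.
#' @param label model label.
#' @return A `regression_fit` list with coefficients, log_likelihood, k,
#'   aic, dispersion, random-effect variances and the lme4 fit in `$fit`.
#' @export
glmm_fit <- function(records, fixed = character(0), fst_to_reference = NULL,
                     label = NULL) {
  d <- records
  if (!is.null(d$missing)) d <- d[!d$missing, , drop = FALSE]
  if (!nrow(d)) stop("no usable genotype records")
  for (v in fixed) {
    if (is.null(d[[v]])) stop(sprintf("predictor column '%s' absent", v))
    d[[paste0("z_", v)]] <- z_transform(d[[v]])
  }
  terms <- if (length(fixed)) paste0("z_", fixed) else character(0)
  if (!is.null(fst_to_reference)) {
    d$z_fst_ref <- z_transform(unname(fst_to_reference[d$population]))
    terms <- c("z_fst_ref", terms)
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (is.null(label))
    label <- if (length(fixed)) paste("Null", paste(fixed, collapse = "+"),
                                      sep = "+") else "Null"
  single_pop <- length(unique(d$population)) < 2
  if (single_pop) {
    f <- stats::as.formula(paste("cbind(derived_count, ancestral_count) ~", rhs))
    fit <- stats::glm(f, family = stats::binomial(), data = d)
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    disp <- sum(stats::residuals(fit, "pearson")^2) / stats::df.residual(fit)
    vc <- c(population = 0, individual = 0)
    conv <- fit$converged
  } else {
    f <- stats::as.formula(paste(
      "cbind(derived_count, ancestral_count) ~", rhs,
      "+ (1 | population) + (1 | individual_id)"))
    fit <- tryCatch(
      lme4::glmer(f, family = stats::binomial(), data = d,
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(structure(list(label = label, converged = FALSE,
                            message = conditionMessage(fit),
                            method = "glmm"), class = "regression_fit"))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    disp <- sum(stats::residuals(fit, "pearson")^2) /
      (nrow(d) - k)
    v <- lme4::VarCorr(fit)
    vc <- c(population = as.numeric(v$population),
            individual = as.numeric(v$individual_id))
    conv <- length(fit@optinfo$conv$lme4) == 0
  }
  structure(list(label = label, fit = fit,
                 coefficients = if (single_pop) stats::coef(fit) else
                   lme4::fixef(fit),
                 log_likelihood = ll, k = k, aic = -2 * ll + 2 * k,
                 dispersion = disp, ranef_var = vc, n = nrow(d),
                 converged = conv, method = "glmm"),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s fit '%s': logLik %.3f, k = %d, AIC %.3f%s\n", x$method,
              x$label, x$log_likelihood, x$k, x$aic,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' @param null_fit,full_fit `regression_fit` objects (full nests null).
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(null_fit, full_fit) {
  if (full_fit$k <= null_fit$k) stop("full model must have more parameters")
  chi2 <- 2 * (full_fit$log_likelihood - null_fit$log_likelihood)
  if (chi2 < -1e-6)
    stop("full model has lower likelihood than null: non-nested or non-converged")
  chi2 <- max(chi2, 0)
  df <- full_fit$k - null_fit$k
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Multi-model comparison table with Akaike weights
#'
#' Ranks candidate models by AIC, computes delta AIC, Akaike weights
#' w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2), cumulative weights, and
#' the 95% best-model confidence set (the smallest prefix of ranked models
#' whose cumulative weight reaches `conf_level`).
#'
#' @param fits list of `regression_fit` objects, or a numeric vector of AIC
#'   values.
#' @param models optional model labels (for a numeric `fits`).
#' @param k optional parameter counts to report.
#' @param use_aicc for `regression_fit` input, use AICc where available.
#' @param conf_level cumulative weight defining the confidence set.
#' @return data.frame with model, rank, aic, delta_aic, akaike_weight,
#'   cumulative_prob, in_confidence_set, k.
#' @export
multimodel_table <- function(fits, models = NULL, k = NULL, use_aicc = FALSE,
                             conf_level = 0.95) {
  if (is.numeric(fits)) {
    aic <- fits
    if (is.null(models)) models <- paste0("model", seq_along(aic))
    if (is.null(k)) k <- rep(NA_integer_, length(aic))
  } else {
    aic <- vapply(fits, function(f)
      if (use_aicc && !is.null(f$aicc)) f$aicc else f$aic, numeric(1))
    models <- vapply(fits, function(f) f$label, character(1))
    k <- vapply(fits, function(f) as.integer(f$k), integer(1))
  }
  if (length(aic) < 2) {
    if (length(aic) == 1)
      return(data.frame(model = models, rank = 1L, aic = aic, delta_aic = 0,
                        akaike_weight = 1, cumulative_prob = 1,
                        in_confidence_set = TRUE, k = k))
    stop("need at least one model")
  }
  bad <- !is.finite(aic)
  if (any(bad)) {
    warning(sprintf("excluding models with non-finite AIC: %s",
                    paste(models[bad], collapse = ", ")))
    aic <- aic[!bad]; models <- models[!bad]; k <- k[!bad]
  }
  ord <- order(aic)
  aic <- aic[ord]; models <- models[ord]; k <- k[ord]
  delta <- aic - aic[1]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  cum <- cumsum(w)
  in_set <- seq_along(w) <= which(cum >= conf_level - 1e-12)[1]
  data.frame(model = models, rank = seq_along(models), aic = aic,
             delta_aic = delta, akaike_weight = w, cumulative_prob = cum,
             in_confidence_set = in_set, k = k, stringsAsFactors = FALSE)
}

#' Leave-one-unit-out stability of a model fit
#'
#' Refits the model with each unit (population by default) excluded and
#' reports the range of each coefficient across refits.
#'
#' @param fit_fun function taking a data subset and returning a
#'   `regression_fit`.
#' @param data data.frame with a column named by `unit`.
#' @param unit grouping column defining the leave-one-out units.
#' @return data.frame with coefficient, original, min, max, n_failed.
#' @export
stability_analysis <- function(fit_fun, data, unit = "population") {
  units <- unique(data[[unit]])
  if (length(units) < 3) stop("need at least 3 units")
  full <- fit_fun(data)
  coefs <- full$coefficients
  mat <- matrix(NA_real_, length(units), length(coefs),
                dimnames = list(units, names(coefs)))
  failed <- character(0)
  for (u in units) {
    f <- tryCatch(fit_fun(data[data[[unit]] != u, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged)) { failed <- c(failed, u); next }
    mat[u, names(f$coefficients)[names(f$coefficients) %in% names(coefs)]] <-
      f$coefficients[names(f$coefficients) %in% names(coefs)]
  }
  data.frame(coefficient = names(coefs), original = as.numeric(coefs),
             min = apply(mat, 2, min, na.rm = TRUE),
             max = apply(mat, 2, max, na.rm = TRUE),
             n_failed = length(failed), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation with t-test P-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r` and two-sided `p` (t distribution, n-2 df).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
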