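test_that("z-transform standardizes and rejects constants", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  z <- z_transform(rnorm(20))
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  lat <- table1_fixture()$populations$latitude
  expect_equal(mean(z_transform(lat)), 0, tolerance = 1e-12)
  expect_equal(sd(z_transform(lat)), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 5)), "constant")
})

test_that("neighbor joining solves the 3-taxon case and recovers additive trees", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- fst_nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 0, B = 2, C = 3))
  # additive 5-taxon distances: exact topology and branch lengths
  set.seed(1)
  true <- ape::rtree(5)
  dd <- ape::cophenetic.phylo(true)
  rec <- fst_nj_tree(dd[true$tip.label, true$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(true), rec), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(rec)[true$tip.label, true$tip.label],
               dd, tolerance = 1e-8)
  expect_error(fst_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("midpoint rooting bisects the longest path", {
  two <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(two)
  expect_equal(r2$edge.length, c(2, 2))
  set.seed(2)
  tr <- ape::rtree(8)
  rooted <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(rooted)[1:8]
  dmax <- max(ape::cophenetic.phylo(tr))
  expect_equal(max(depths), dmax / 2, tolerance = 1e-8)
})

test_that("PGLS equals OLS on a star tree and the GLS closed form in general", {
  set.seed(3)
  n <- 8
  star <- ape::stree(n, type = "star")
  star$tip.label <- sprintf("P%02d", 1:n)
  star$edge.length <- rep(1, n)
  dat <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                    row.names = star$tip.label)
  fit <- pgls_fit(y ~ x1 + x2, dat, star)
  ols <- lm(y ~ x1 + x2, dat)
  expect_equal(fit$coefficients, coef(ols), tolerance = 1e-8,
               ignore_attr = TRUE)
  # structured tree: coefficients equal the explicit GLS oracle
  tree <- midpoint_root(ape::rtree(6))
  tree$tip.label <- sprintf("P%02d", 1:6)
  dat2 <- data.frame(y = rnorm(6), x1 = rnorm(6),
                     row.names = tree$tip.label)
  fit2 <- pgls_fit(y ~ x1, dat2, tree)
  C <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  X <- cbind(1, dat2[tree$tip.label, "x1"])
  y <- dat2[tree$tip.label, "y"]
  beta <- solve(t(X) %*% solve(C) %*% X, t(X) %*% solve(C) %*% y)
  expect_equal(unname(fit2$coefficients), as.numeric(beta), tolerance = 1e-10)
  # an all-zero predictor changes k but not the likelihood
  fit3 <- pgls_fit(y ~ x1 + offsetcol, transform(dat2, offsetcol = 0 * y),
                   tree)
  expect_equal(fit3$log_likelihood, fit2$log_likelihood, tolerance = 1e-8)
  expect_equal(fit3$k, fit2$k + 1)
  # lambda = 0 strips the off-diagonal covariance: weighted OLS
  fit0 <- pgls_fit(y ~ x1, dat2, tree, lambda = 0)
  w <- 1 / diag(C)
  wls <- lm(y ~ x1, dat2[tree$tip.label, ], weights = w)
  expect_equal(unname(fit0$coefficients), unname(coef(wls)),
               tolerance = 1e-8)
})

test_that("PGLS log-likelihood agrees with gls(corBrownian) as an oracle", {
  skip_if_not_installed("nlme")
  set.seed(4)
  # ultrametric tree: corBrownian (a correlation structure) then spans the
  # same model as the full Brownian covariance
  tree <- ape::rcoal(10)
  tree$tip.label <- sprintf("P%02d", 1:10)
  dat <- data.frame(y = rnorm(10), x = rnorm(10), row.names = tree$tip.label)
  fit <- pgls_fit(y ~ x, dat, tree)
  g <- suppressWarnings(nlme::gls(y ~ x, dat,
                                  correlation = ape::corBrownian(1, tree,
                                                                 form = ~1),
                                  method = "ML"))  # tip-order notice
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(g)),
               tolerance = 1e-6)
})

test_that("binomial GLMM reduces to a GLM for one population and recovers
           the pooled frequency", {
  set.seed(5)
  der <- rbinom(200, 2, 0.3)
  recs <- data.frame(individual_id = sprintf("i%03d", 1:200),
                     population = "A", derived_count = der,
                     ancestral_count = 2 - der, latitude = 10)
  fit <- glmm_fit(recs)
  expect_equal(unname(fit$coefficients[1]), qlogis(mean(der) / 2),
               tolerance = 1e-8)
  expect_equal(fit$ranef_var, c(population = 0, individual = 0))
})

test_that("GLMM with ancient-sample predictors supports the 8-model set", {
  preds <- c("latitude", "temperature", "age_years")
  subsets <- unlist(lapply(0:3, function(k)
    utils::combn(preds, k, simplify = FALSE)), recursive = FALSE)
  expect_length(subsets, 8)
  anc <- generate_ancient_samples(60, trajectory = function(a) 0.6, seed = 6)
  anc$temperature <- 20 - 0.2 * anc$latitude + rnorm(60)
  anc$population <- rep(c("HG", "EF", "SP"), 20)
  fit <- glmm_fit(anc, fixed = c("latitude", "age_years"))
  expect_true(!is.null(fit$log_likelihood))
})

test_that("likelihood-ratio test has the right df, null value and oracle", {
  f0 <- structure(list(label = "null", log_likelihood = -10, k = 4,
                       converged = TRUE), class = "regression_fit")
  f1 <- structure(list(label = "full", log_likelihood = -10, k = 6,
                       converged = TRUE), class = "regression_fit")
  l <- lrt(f0, f1)
  expect_equal(l$chi2, 0); expect_equal(l$df, 2); expect_equal(l$p, 1)
  # Gaussian toy with closed-form MLEs
  set.seed(7)
  y <- rnorm(50); x <- rnorm(50)
  ll <- function(res, n) -n / 2 * (log(2 * pi) + log(mean(res^2)) + 1)
  r0 <- y - mean(y); r1 <- residuals(lm(y ~ x))
  chi2_oracle <- 2 * (ll(r1, 50) - ll(r0, 50))
  g0 <- structure(list(log_likelihood = ll(r0, 50), k = 2, converged = TRUE),
                  class = "regression_fit")
  g1 <- structure(list(log_likelihood = ll(r1, 50), k = 3, converged = TRUE),
                  class = "regression_fit")
  expect_equal(lrt(g0, g1)$chi2, chi2_oracle, tolerance = 1e-10)
  expect_error(lrt(f1, f0), "more parameters")
})

test_that("LRT is invariant to z-transforming predictors", {
  set.seed(8)
  pan <- generate_cline_panel(cline_scenario(n_pops = 8, n_individuals = 25,
                                             beta_lat = 0.8, seed = 8))
  raw <- pan$records
  fit_z <- glmm_fit(raw, fixed = "latitude")
  raw2 <- raw
  raw2$latitude <- raw2$latitude * 3 + 100  # affine change absorbed by z
  fit_z2 <- glmm_fit(raw2, fixed = "latitude")
  null <- glmm_fit(raw)
  expect_equal(lrt(null, fit_z)$chi2, lrt(null, fit_z2)$chi2,
               tolerance = 1e-6)
})

test_that("multimodel table reproduces printed Akaike weights and behaves", {
  fx <- table1_fixture()
  tab <- multimodel_table(fx$aic$pgls_1kgp$aic, fx$aic$pgls_1kgp$model,
                          k = fx$aic$pgls_1kgp$k)
  expect_equal(round(tab$akaike_weight, 3), c(0.504, 0.446, 0.036, 0.014))
  expect_equal(tab$in_confidence_set, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(tab$akaike_weight), 1)
  expect_equal(tab$delta_aic[1], 0)
  # permutation invariance
  perm <- sample(4)
  tab2 <- multimodel_table(fx$aic$pgls_1kgp$aic[perm],
                           fx$aic$pgls_1kgp$model[perm])
  expect_equal(tab2$model, tab$model)
  expect_equal(tab2$akaike_weight, tab$akaike_weight)
  # single model and non-finite exclusion
  expect_equal(multimodel_table(100, "only")$akaike_weight, 1)
  expect_warning(t3 <- multimodel_table(c(1, 2, Inf),
                                        c("a", "b", "bad")), "non-finite")
  expect_equal(nrow(t3), 2)
})

test_that("leave-one-out stability flags the influential unit", {
  set.seed(9)
  base <- generate_cline_panel(cline_scenario(n_pops = 8, n_individuals = 30,
                                              beta_lat = 1, seed = 9))
  recs <- base$records
  # an exact replica population: excluding it barely moves the fit
  rep_pop <- recs[recs$population == "P04", ]
  rep_pop$population <- "P99"
  rep_pop$individual_id <- sub("P04", "P99", rep_pop$individual_id)
  recs2 <- rbind(recs, rep_pop)
  fit_fun <- function(d) glmm_fit(d, fixed = "latitude")
  st <- stability_analysis(fit_fun, recs2)
  expect_equal(nrow(st), 2)  # intercept + latitude
  lat_row <- st[st$coefficient == "z_latitude", ]
  expect_true(lat_row$min <= lat_row$original &&
                lat_row$original <= lat_row$max)
  # outlier population produces the widest excursion
  out <- recs
  out$derived_count[out$population == "P08"] <- 0
  out$ancestral_count[out$population == "P08"] <- 2
  fits <- vapply(unique(out$population), function(u)
    fit_fun(out[out$population != u, ])$coefficients[["z_latitude"]],
    numeric(1))
  full <- fit_fun(out)$coefficients[["z_latitude"]]
  dev <- abs(fits - full)
  expect_equal(names(which.max(dev)), "P08")
})

test_that("pearson correlation matches the textbook formula", {
  x <- c(1, 3, 4, 6, 8, 9, 11, 14, 17, 20)
  y <- 2 * x
  expect_equal(pearson_correlation(x, y)$r, 1)
  set.seed(10)
  y2 <- rnorm(10)
  r_formula <- sum((x - mean(x)) * (y2 - mean(y2))) /
    sqrt(sum((x - mean(x))^2) * sum((y2 - mean(y2))^2))
  pc <- pearson_correlation(x, y2)
  expect_equal(pc$r, r_formula, tolerance = 1e-12)
  tstat <- r_formula * sqrt(8 / (1 - r_formula^2))
  expect_equal(pc$p, 2 * pt(-abs(tstat), 8), tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 10)), "zero variance")
})
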