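test_that("summary vector matches standalone statistics and applies the
           exclusion filter", {
  dem <- gravel_demography("EUR")
  set.seed(2)
  spec <- selection_model_spec("SSV", t_sel = 30000, s_NA = 0.03,
                               f_sel = 0.15)
  sim <- simulate_locus(spec, dem)
  m <- genetic_map(c(1, 185000), c(1.2, 1.2))
  sv <- compute_sumstat_vector(sim$hm, sim$focal_position, m)
  expect_false(sv$excluded)
  expect_length(sv$stats, 14)
  rows_na <- which(sim$hm$population == "NONAFR")
  central <- sim$hm$positions >= 60000 & sim$hm$positions <= 125000
  expect_equal(sv$stats[["tajd_nonafr_central"]],
               tajimas_d_matrix(sim$hm, rows_na, which(central)))
  expect_equal(sv$stats[["fwh_nonafr_flanks"]],
               fay_wu_h(sfs_from_matrix(sim$hm, rows_na, which(!central)),
                        length(rows_na)))
  expect_equal(sv$stats[["daf_nonafr"]],
               mean(sim$hm$alleles[rows_na, site_index(sim$hm,
                                                       sim$focal_position)]))
  expect_equal(sv$stats[["xpehh_core"]],
               xpehh_site(hm_subset(sim$hm, rows_na),
                          hm_subset(sim$hm, which(sim$hm$population == "AFR")),
                          sim$focal_position, m))
  # exclusion: rare derived allele in the test deme
  al <- cbind(matrix(rbinom(40 * 6, 1, 0.4), 40), c(1, rep(0, 39)))
  hm <- haplotype_matrix(al, c(1:6 * 10000, 92500),
                         rep(sprintf("i%02d", 1:20), each = 2),
                         rep(c("AFR", "NONAFR"), each = 20))
  expect_true(compute_sumstat_vector(hm, 92500, m)$excluded)
})

test_that("Box-Cox + PLS transform is well-behaved", {
  ref <- toy_ref(300)
  tr <- fit_transform(ref, n_components = 5)
  # already-Gaussian statistics: lambda close to 1
  expect_true(all(abs(tr$lambda - 1) < 0.6))
  Z <- project_stats(tr, ref)
  expect_equal(dim(Z), c(900L, 5L))
  # projecting the training rows reproduces the stored variates
  expect_lt(max(abs(Z - tr$pls$variates$X)), 1e-8)
  # a constant statistic is dropped with a warning
  ref2 <- ref; ref2$fst_focal <- 1
  expect_warning(tr2 <- fit_transform(ref2), "constant")
  expect_false("fst_focal" %in% tr2$stat_cols)
})

test_that("PLS captures a rank-1 parameter-statistic relationship", {
  set.seed(3)
  ref <- toy_ref(400, shift = c(SDN = 0, SSV = 0, NTR = 0))
  # make s_NA perfectly encoded in a linear combination of two statistics
  ref$s_NA <- ref$xpehh_core + 2 * ref$fst_central
  out <- rmse_per_component(ref, max_components = 4)
  expect_lt(out[1, "s_NA"] / sd(ref$s_NA), 0.2)
  # pure-noise parameter: flat curve
  expect_lt(diff(range(out[, "f_sel"])) / sd(ref$f_sel), 0.2)
})

test_that("rejection retains the exact nearest neighbours", {
  ref <- toy_ref(200)
  tr <- fit_transform(ref)
  obs <- unlist(ref[17, sumstat_columns(ref)])
  ret <- abc_reject(obs, ref, tr, n_retain = 25)
  expect_equal(ret$distance[1], 0, tolerance = 1e-8)
  expect_equal(rownames(ret)[1], "17")
  # brute-force k-NN oracle in the projected space
  Z <- project_stats(tr, ref)
  d <- sqrt(colSums((t(Z) - Z[17, ])^2))
  expect_equal(sort(ret$distance), unname(sort(d)[1:25]), tolerance = 1e-8)
  all_ret <- abc_reject(obs, ref, tr, n_retain = nrow(ref))
  expect_equal(nrow(all_ret), nrow(ref))
  expect_error(abc_reject(obs, ref, tr, n_retain = nrow(ref) + 1), "smaller")
})

test_that("model posteriors correct for unequal simulation effort", {
  retained <- data.frame(model = c(rep("SDN", 50), rep("SSV", 40),
                                   rep("NTR", 10)))
  counts <- c(SDN = 10000, SSV = 10000, NTR = 1000)
  mp <- model_posterior(retained, counts)
  raw <- c(50 / 10000, 40 / 10000, 10 / 1000)
  expect_equal(unname(mp$posterior), raw / sum(raw))
  expect_equal(sum(mp$posterior), 1)
  # retained proportional to simulated counts: uniform posterior
  prop <- data.frame(model = c(rep("SDN", 100), rep("SSV", 100),
                               rep("NTR", 10)))
  expect_equal(unname(model_posterior(prop, counts)$posterior), rep(1 / 3, 3))
  # all retained from one model
  one <- data.frame(model = rep("SSV", 30))
  mp1 <- model_posterior(one, counts)
  expect_equal(unname(mp1$posterior["SSV"]), 1)
  expect_equal(mp1$bayes_factor, Inf)
  expect_error(model_posterior(retained, c(SDN = 0, SSV = 1, NTR = 1)),
               "> 0")
})

test_that("the Bayes factor / posterior identity matches the published rows", {
  expect_equal(round(bayes_factor_to_posterior(9.6), 3), 0.906)
  expect_equal(round(bayes_factor_to_posterior(3.1), 3), 0.756)
  expect_equal(bayes_factor_to_posterior(1), 0.5)
})

test_that("parameter posteriors are order statistics of the retained set", {
  ret <- data.frame(model = "SSV", t_sel = rep(26000, 40),
                    s_NA = seq(0, 1, length.out = 40),
                    f_sel = runif(40))
  pp <- parameter_posterior(ret, "SSV")
  expect_equal(pp$median[pp$parameter == "t_sel"], 26000)
  expect_equal(pp$q975[pp$parameter == "t_sel"], 26000)
  srow <- pp[pp$parameter == "s_NA", ]
  expect_lt(abs(srow$median - 0.5), 0.02)
  expect_lt(abs(srow$q025 - 0.025), 0.05)
  small <- parameter_posterior(ret[1:10, ], "SSV")
  expect_true(attr(small, "low_confidence"))
})

test_that("cross-validation is at chance for identical generators and near
           perfect for separated ones", {
  # two relabeled copies of the same cloud: ~50% correct
  ref_same <- toy_ref(250, shift = c(A = 0, B = 0, NTR = 99), seed = 4)
  ref_same <- ref_same[ref_same$model != "NTR", ]
  cv_same <- cross_validation_power(ref_same, n_pseudo = 60,
                                    accept_frac = 0.02)
  expect_true(all(abs(cv_same$fraction_correct - 0.5) < 0.2))
  # well-separated clouds: near 100%
  ref_sep <- toy_ref(250, shift = c(SDN = 8, SSV = 0, NTR = -8), sd = 0.5,
                     seed = 5)
  cv_sep <- cross_validation_power(ref_sep, n_pseudo = 60,
                                   accept_frac = 0.02)
  expect_true(all(cv_sep$fraction_correct > 0.95))
  expect_equal(unname(rowSums(cv_sep$confusion)), rep(60, 3))
  expect_equal(cv_sep$tp_fp_fn$TP + cv_sep$tp_fp_fn$FN, rep(60L, 3))
})

test_that("halted comparison requires halted tables and runs the two sets", {
  ref <- toy_ref(200)
  obs <- unlist(ref[5, sumstat_columns(ref)])
  expect_error(run_halted_comparison(ref, obs), "absent")
  ref_h <- toy_ref(200, shift = c(SDN_halted = 3, SSV_halted = 0.5,
                                  NTR = -3), seed = 6)
  full <- rbind(ref, ref_h)
  out <- run_halted_comparison(full, obs, n_retain = 50)
  expect_setequal(names(out), c("halted", "all_models"))
  expect_equal(sum(out$halted$posterior), 1)
  expect_equal(length(out$all_models$posterior), 5)
})
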