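test_that("demography converts years to generations and shapes the demes", {
  dem <- gravel_demography("EUR")
  expect_equal(dem$t_ooa, 51000 / 25)
  expect_equal(dem$t_split, 23000 / 25)
  expect_length(dem$sizes1, dem$t_ooa)
  expect_equal(dem$sizes1[dem$t_split + 1], 1861)
  eas <- gravel_demography("EAS")
  # branches differ only in the daughter deme parameters
  expect_equal(eas$sizes0, dem$sizes0)
  expect_equal(eas$t_ooa, dem$t_ooa)
  expect_false(isTRUE(all.equal(eas$sizes1[1], dem$sizes1[1])))
  expect_equal(dem$n_demes, 2L)
})

test_that("prior draws respect their supports and are uniform", {
  set.seed(1)
  sdn <- replicate(3000, unlist(sample_prior("SDN")[c("t_sel", "s_A", "s_NA")]))
  expect_true(all(sdn["s_NA", ] >= 0.005 & sdn["s_NA", ] <= 0.05))
  expect_true(all(sdn["s_A", ] <= 0.015))
  expect_true(all(sdn["t_sel", ] >= 30000 & sdn["t_sel", ] <= 60000))
  expect_gt(stats::ks.test((sdn["s_NA", ] - 0.005) / 0.045, "punif")$p.value,
            0.01)
  ntr <- sample_prior("NTR")
  expect_equal(ntr$s_A, 0); expect_equal(ntr$s_NA, 0)
  ssv <- replicate(200, sample_prior("SSV")$t_sel)
  expect_true(all(ssv >= 21000 & ssv <= 51000))
  expect_equal(sample_prior("SSV_halted")$halt_age, 3000)
})

test_that("deterministic trajectories follow the logistic recursion", {
  dem <- constant_demography(10000)
  spec <- selection_model_spec("SDN", t_sel = 100 * 25, s_A = 0.02)
  tr <- simulate_trajectory(spec, dem, deterministic = TRUE)
  oracle <- wf_deterministic(1 / 20000, 0.02, 0.5, 100)
  expect_equal(rev(tr$x0), oracle, tolerance = 1e-12)
  # s = 0: frequency constant
  ntr <- selection_model_spec("NTR", t_sel = 2500)
  tr0 <- simulate_trajectory(ntr, dem, deterministic = TRUE)
  expect_true(all(abs(tr0$x0 - tr0$x0[1]) < 1e-15))
})

test_that("SSV trajectories hit f_sel exactly at onset and stay in [0,1]", {
  dem <- gravel_demography("EUR")
  set.seed(2)
  spec <- selection_model_spec("SSV", t_sel = 30000, s_NA = 0.02,
                               f_sel = 0.13)
  tr <- simulate_trajectory(spec, dem)
  onset <- 30000 / 25
  expect_equal(tr$x0[onset + 1], 0.13)
  expect_equal(tr$x1[onset + 1], 0.13)
  expect_true(all(tr$x0 >= 0 & tr$x0 <= 1))
  expect_gt(tr$x0[tr$g_birth + 1], 0)        # born at positive frequency
  expect_gt(max(tr$x0[1], tr$x1[1]), 0)      # survives to the present
})

test_that("halted selection zeroes the most recent generations' coefficient", {
  dem <- gravel_demography("EUR")
  spec <- selection_model_spec("SDN_halted", t_sel = 40000, s_A = 0,
                               s_NA = 0.0105, halt_age = 3000)
  # deterministic run: inside the halted window the non-African frequency
  # moves only by (tiny) migration; before it, selection moves it visibly
  tr <- simulate_trajectory(spec, dem, deterministic = TRUE)
  halt_gen <- 3000 / 25
  recent <- max(abs(diff(tr$x1[1:halt_gen])))
  older <- max(abs(diff(tr$x1[(halt_gen + 2):(halt_gen + 30)])))
  expect_lt(recent, 1e-4)
  expect_gt(older, 20 * recent)
})

test_that("trajectories are deterministic under a fixed seed and report rejections", {
  dem <- gravel_demography("EAS")
  spec <- selection_model_spec("SDN", t_sel = 35000, s_A = 0.001,
                               s_NA = 0.01)
  set.seed(3); t1 <- simulate_trajectory(spec, dem)
  set.seed(3); t2 <- simulate_trajectory(spec, dem)
  expect_identical(t1$x0, t2$x0)
  expect_identical(t1$x1, t2$x1)
  expect_gte(t1$n_lost, 0)
})

test_that("hotspot extension conserves genetic length and masks the excess", {
  L <- 100000
  flat <- genetic_map(c(1, L), c(1.5, 1.5))
  ext0 <- apply_hotspot_extension(flat, L)
  expect_equal(ext0$L_ext, L)
  expect_equal(nrow(ext0$mask), 0)
  expect_equal(ext0$to_original(c(5, 500, 99999)), c(5, 500, 99999))

  # one 1 kb hotspot at 10x the baseline
  m <- genetic_map(c(1, 50000, 51000, L), c(2, 20, 2, 2))
  ext <- apply_hotspot_extension(m, L)
  expect_equal(ext$rate0, 2)
  expect_equal(ext$L_ext, L + 9000)
  total_cm <- function(map, Lx) map_cm(map, Lx) - map_cm(map, 1)
  expect_equal(ext$rate0 * (ext$L_ext - 1) / 1e6, total_cm(m, L),
               tolerance = 1e-9)
  # mask covers exactly the inserted excess and projection inverts
  expect_equal(unname(ext$mask[, 2] - ext$mask[, 1]), 9000)
  inside <- mean(ext$mask[1, ])
  expect_true(is.na(ext$to_original(inside)))
  probes <- c(10, 49999, 51500, 99000)
  expect_equal(ext$to_original(ext$to_extended(probes)), probes)
  hot_everywhere <- genetic_map(c(1, L), c(9, 9))
  expect_error(apply_hotspot_extension(hot_everywhere, L), "hotspot")
})

test_that("neutral simulations match closed-form coalescent expectations", {
  set.seed(4)
  dem <- constant_demography(10000)
  L <- 50000; mu <- 1.25e-8; n <- 20
  reps <- 500
  S <- numeric(reps); D <- numeric(reps); P <- numeric(reps)
  for (i in seq_len(reps)) {
    sim <- simulate_locus(NULL, dem, L = L, n_hap = c(n, 0), mu = mu)
    S[i] <- ncol(sim$hm$alleles)
    D[i] <- tajimas_d_matrix(sim$hm)
    P[i] <- if (ncol(sim$hm$alleles)) nucleotide_diversity(sim$hm) else 0
  }
  theta <- 4 * 10000 * mu * L
  expect_lt(abs(mean(S) / (theta * sum(1 / (1:(n - 1)))) - 1), 0.05)
  expect_lt(abs(mean(P) / theta - 1), 0.05)
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.1)
})

test_that("zero mutation rate yields zero segregating sites", {
  dem <- constant_demography(5000)
  set.seed(5)
  sim <- simulate_locus(NULL, dem, L = 20000, n_hap = c(10, 0), mu = 0)
  expect_equal(ncol(sim$hm$alleles), 0L)
})

test_that("strong selection drives the derived allele up in the selected deme", {
  dem <- gravel_demography("EUR")
  set.seed(6)
  wins <- 0L; usable <- 0L
  while (usable < 60) {
    spec <- selection_model_spec("SDN", t_sel = 45000, s_A = 0,
                                 s_NA = 0.05)
    tr <- simulate_trajectory(spec, dem)
    # condition on the allele segregating in the test deme, as the
    # XP-EHH record filter does
    if (tr$x1[1] <= 0.05) next
    usable <- usable + 1L
    if (tr$x1[1] > tr$x0[1]) wins <- wins + 1L
  }
  expect_gte(wins / usable, 0.9)
})

test_that("locus simulation is reproducible and focal counts match the trajectory", {
  dem <- gravel_demography("EUR")
  spec <- selection_model_spec("SSV", t_sel = 30000, s_NA = 0.03,
                               f_sel = 0.1)
  set.seed(7); s1 <- simulate_locus(spec, dem, L = 40000, n_hap = c(40, 40))
  set.seed(7); s2 <- simulate_locus(spec, dem, L = 40000, n_hap = c(40, 40))
  expect_identical(s1$hm$alleles, s2$hm$alleles)
  expect_identical(s1$hm$positions, s2$hm$positions)
  j0 <- site_index(s1$hm, s1$focal_position)
  daf_afr <- mean(s1$hm$alleles[s1$hm$population == "AFR", j0])
  # sampled counts are a binomial draw around the trajectory endpoint
  expect_lt(abs(daf_afr - s1$trajectory$x0[1]), 0.25)
})

test_that("standing variation carries more derived-haplotype diversity than
           a fresh sweep", {
  dem <- gravel_demography("EUR")
  set.seed(8)
  m <- genetic_map(c(1, 80000), c(1.2, 1.2))
  ihh_of <- function(model) {
    vals <- c()
    while (length(vals) < 12) {
      spec <- if (model == "SDN")
        selection_model_spec("SDN", t_sel = runif(1, 30000, 60000),
                             s_A = 0.005, s_NA = 0.02)
      else selection_model_spec("SSV", t_sel = runif(1, 21000, 51000),
                                s_NA = 0.02, f_sel = 0.15)
      sim <- simulate_locus(spec, dem, map = m, L = 80000,
                            n_hap = c(60, 60), min_test_daf = 0.05)
      if (isTRUE(sim$excluded)) next
      e <- ehh_and_ihh(sim$hm, sim$focal_position, 1L, m,
                       rows = which(sim$hm$population == "NONAFR"))
      if (isTRUE(e$defined)) vals <- c(vals, e$ihh)
    }
    vals
  }
  expect_gt(mean(ihh_of("SDN")), mean(ihh_of("SSV")))
})
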