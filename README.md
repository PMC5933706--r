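# clineselect

Tools for resolving whether a candidate SNP's allele-frequency cline across
populations reflects local adaptation — written for population geneticists
analysing a single locus against a genome-wide background.

Given phased genotypes, population metadata (latitude, longitude, annual
mean temperature, sample sizes) and a recombination map, the package
implements the full inference chain:

* **Selection scans** — per-site Weir–Cockerham F_ST
  (θ = a/(a+b+c) from the 1984 variance components; genome-wide values as
  the ratio of averages Σa/Σ(a+b+c)), EHH/iHH, iHS
  (ln iHH_A/iHH_D, standardized in 2% DAF bins), XP-EHH
  (ln iHH_test/iHH_ref), and rank-based empirical P-values.
* **Ancestry-controlled cline regressions** — PGLS with Brownian
  covariance on a midpoint-rooted NJ tree of the pairwise F_ST matrix, and
  binomial logit GLMMs on two-column allele counts with population and
  individual random intercepts; model sets compared with AIC(c), Akaike
  weights and the 95% confidence set.
* **Allele-origin inference** — linked nucleotide diversity among
  derived-allele haplotypes after filtering recombinants (median pairwise
  difference rule).
* **ABC model choice and estimation** — a trajectory-conditioned
  structured-coalescent simulator (two-deme out-of-Africa demography,
  Wright–Fisher trajectories with additive selection, recombination,
  hotspot extension) generates reference tables under selection-on-de-novo
  -mutation (SDN), selection-on-standing-variation (SSV), neutral (NTR)
  and halted variants; Box-Cox + PLS-transformed 14-statistic summaries
  and rejection sampling give posterior model probabilities
  (BF = PP/(1−PP)), parameter posteriors, and cross-validated power.
* **Synthetic-data generators** — clinal genotype panels, Balding–Nichols
  background SNPs, ancient samples, prevalence tables — so the entire
  pipeline is testable offline.

## Worked example

Reproduce the headline population-differentiation number from printed
allele frequencies (derived allele at 87% in 61 Finnish diploids vs 5% in
61 Yoruba diploids, heterozygosity under Hardy–Weinberg):

```r
library(clineselect)

fst <- wc_fst_site(site_counts(n = c(61, 61), derived_count = c(106, 6)))
fst$theta
#> [1] 0.8053637
```

A θ of 0.805 between two populations is extreme — genome-wide pairwise
human F_ST is typically ~0.1 — which is what places this SNP in the far
tail of the empirical distribution.

Fit the cline models on a synthetic panel and compare them:

```r
sc  <- cline_scenario(n_pops = 20, n_individuals = 61, beta_lat = 1, seed = 1)
pan <- generate_cline_panel(sc)
bg  <- generate_background(sc)

res <- run_cline(pan$records, pan$meta, bg$fst_matrix,
                 method = "glmm", reference_pop = "P01")
res$table[, c("model", "aic", "delta_aic", "akaike_weight",
              "in_confidence_set")]
#>                       model      aic delta_aic akaike_weight in_confidence_set
#> 1             Null+latitude 2271.879  0.000000  6.992279e-01              TRUE
#> 2 Null+latitude+temperature 2273.569  1.690363  3.003040e-01              TRUE
#> 3          Null+temperature 2286.497 14.618013  4.681204e-04             FALSE
#> 4                      Null 2322.031 50.152144  8.999514e-12             FALSE
```

The latitude model ranks first (Akaike weight 0.70, with the
latitude+temperature model completing the 95% confidence set) and the null
model — drift and shared ancestry only — is decisively rejected: the
simulated latitude effect is recovered. Akaike weights are exp(−Δᵢ/2)
normalized over the model set.

ABC model choice on simulated data:

```r
dem <- gravel_demography("EUR")
ref <- rbind(build_reference_table("SDN", 2000, dem),
             build_reference_table("SSV", 2000, dem),
             build_reference_table("NTR", 2000, dem))

spec <- selection_model_spec("SSV", t_sel = 30000, s_NA = 0.02, f_sel = 0.1)
sim  <- simulate_locus(spec, dem)
obs  <- compute_sumstat_vector(sim$hm, sim$focal_position,
                               genetic_map(c(1, 185000), c(1.2, 1.2)))
out  <- run_abc(obs$stats, ref)
out$model_choice$posterior   # posterior probability per model
out$parameters               # median and 95% interval for t_sel, s_NA, f_sel
```

A command-line wrapper over these functions is installed at
`inst/cli/clineselect.R` (subcommands `synth`, `scan`, `cline`, `origin`).

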