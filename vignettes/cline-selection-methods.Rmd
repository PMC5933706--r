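---
title: "Models and methods: detecting clinal local adaptation at a candidate SNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detecting clinal local adaptation at a candidate SNP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clineselect)
```

# The scientific problem

A biallelic SNP whose derived allele frequency rises with latitude across
human populations is a candidate for temperature-related local adaptation.
Demonstrating adaptation requires ruling out two confounders: shared
ancestry (northern populations are also phylogenetically closer to each
other) and genetic drift. `clineselect` implements the full inference chain
for this problem:

1. **Selection scans** — per-SNP Weir–Cockerham F_ST against a reference
   population, haplotype statistics (EHH, iHS, XP-EHH), and empirical
   P-values against a genome-wide background.
2. **Cline regressions with ancestry control** — phylogenetic generalized
   least squares (PGLS) on a neighbor-joining tree built from the pairwise
   genome-wide F_ST matrix, and binomial logit GLMMs on individual allele
   counts, compared by AIC multi-model inference.
3. **Haplotype-based allele-origin inference** — linked diversity among
   derived-allele haplotypes after filtering recombinants.
4. **ABC model choice** — does the data favour selection on a de novo
   mutation (SDN), selection on standing variation (SSV), or neutrality
   (NTR)? A trajectory-conditioned coalescent simulator provides the
   forward model; Box-Cox + PLS-transformed summary statistics and
   rejection sampling provide the inference.

# Statistics

**Weir–Cockerham F_ST.** `wc_fst_site()` computes the 1984 variance
components a (among populations), b (among individuals within populations)
and c (within individuals), with unequal sample sizes entering through
n_c, and theta = a/(a+b+c). When only allele frequencies are available
(e.g. when reproducing published tables), observed heterozygosity is
imputed under Hardy–Weinberg as 2p(1−p); with genotypes, observed
heterozygote counts are used. Genome-wide F_ST between two populations is
the *ratio of averages*, sum(a)/sum(a+b+c) over sites polymorphic in the
pair — never the mean of per-site ratios, which weights uninformative
sites equally.

**Haplotype statistics.** EHH around a core allele is the probability that
two randomly drawn carrier haplotypes are identical over the interval from
the core to a position x. It is followed outward until it drops below 0.05
(configurable) and integrated against genetic distance to give iHH. iHS is
ln(iHH_ancestral/iHH_derived), standardized within 2% derived-allele-
frequency bins; XP-EHH is ln(iHH_test/iHH_reference) over all haplotypes
of each panel, standardized genome-wide. Sites with derived allele
frequency below 5% (or above 95% for iHS) are excluded, because rare
alleles break up haplotype homozygosity without carrying information about
sweeps. Monomorphic sites are excluded from the integration grid, so the
statistics are invariant to padding the matrix with invariant columns.

**Empirical P-values** are plain rank proportions against the background
distribution, with no +1 smoothing: the published headline value (an
F_ST in the 0.02% tail) is a plain proportion, and this convention
reproduces it.

# Cline models

Predictors (latitude, absolute value in the southern hemisphere;
annual mean temperature; sample age for ancient panels) are z-transformed.

**PGLS.** The response is the per-population mean derived allele
frequency. Residual covariance is sigma^2 C with C_ij the shared
root-to-MRCA path length on the midpoint-rooted NJ tree of the pairwise
F_ST matrix; Pagel's lambda scales the off-diagonal entries and is fixed
at 1 by default (the common default in comparative methods; an ML-lambda
option would add a parameter without changing the model ranking on our
synthetic panels). Estimation is ML so the null/full likelihood-ratio
test is valid, and AICc (small-sample correction) is used for model
ranking across the four candidate models (Null, +Lat, +Temp, +Temp+Lat).
The parameter count k of the null model is a reporting convention
(published tables use k = 4); Akaike weights depend only on AIC
differences, so the convention does not affect the ranking.

**GLMM.** Each individual contributes a two-column response (derived,
ancestral allele counts). Fixed effects: z-scored genome-wide F_ST to the
reference population (shared-ancestry control) plus the test predictors.
Random intercepts: population (drift) and individual (the
observation-level effect absorbing overdispersion and the
non-independence of an individual's two alleles). Fitting is
Laplace-approximated ML via `lme4::glmer`, so AICs are comparable across
fixed-effect structures; the dispersion parameter (sum of squared Pearson
residuals over residual df) is reported. With one population the model
degenerates to a binomial GLM. For ancient panels, age joins the
predictor set (8 models instead of 4) and the F_ST covariate is off by
default, since a single reference-anchored distance is not meaningful for
temporally heterogeneous samples.

**Multi-model inference.** Akaike weights w_i = exp(−Δ_i/2)/Σexp(−Δ_j/2);
models are ranked, cumulative weights computed, and the 95% confidence set
is the shortest prefix reaching 0.95. Model stability is assessed by
leave-one-population-out refits reporting the range of each coefficient.

# The locus simulator

The ABC forward model simulates 185 kb of sequence for 122 + 122
chromosomes from an African and one non-African population under a
two-deme out-of-Africa demography (ancestral size 7,310; African expansion
to 14,474 at 148 kya; out-of-Africa bottleneck of 1,861 at 51 kya;
European/East-Asian daughter growing exponentially from 1,032/554 after
23 kya; asymmetrically scaled migration; generation time 25 years). These
are the published point estimates of the standard out-of-Africa model and
all are configurable.

Selection models:

* **SDN** — the allele appears as a single copy in Africa at t_sel ~
  U(30, 60) kya, immediately advantageous with s_A ~ U(0, 1.5%) in Africa
  and s_NA ~ U(0.5%, 5%) outside.
* **SSV** — a neutral standing allele at frequency f_sel ~ U(0, 20%)
  becomes advantageous (s_NA ~ U(0, 5%]) in the non-African deme at
  t_sel ~ U(21, 51) kya; the pre-onset history is built backward from
  f_sel by neutral binomial sampling conditioned on loss into the past,
  and the onset frequency applies to both demes (the allele is a shared
  standing variant). Selection stays 0 in Africa.
* **NTR** — as SDN with all selection coefficients 0.
* **Halted variants** — identical except the selection coefficient becomes
  0 for the most recent 3,000 years.

Fitness is additive: genotype fitnesses 1, 1+hs, 1+s with h = 0.5.
Trajectories are forward Wright–Fisher binomial draws with selection and
migration; trajectories losing the allele before the present are rejected
and redrawn (counts are reported, because this rejection — like the
XP-EHH computability filter below — reshapes the effective prior).

Haplotypes are generated by a **trajectory-conditioned structured
coalescent**: backward in time, generation by generation, lineages are
partitioned by deme and focal-allele class; class sizes follow the
realized trajectory (2N_d(t)·x_d(t)); parents are drawn
Wright–Fisher-style within each class, so multiple mergers during
bottlenecks are handled exactly; recombination splits a lineage's
ancestral material at a uniform point, the piece on the focal side keeping
the class and the other piece redrawing it from the current class
frequency; at the allele's birth the remaining derived lineages coalesce
into the founding copy and join the ancestral background. Once the sample
is in a single deme with no derived-class lineages, simulation switches to
the continuous-time coalescent for the ancient phase. Mutations are laid
down at rate mu per bp per generation on the ancestral material
(infinite-sites, continuous positions discretized at output). The default
mutation rate is 1.25e-8 /bp/generation, a standard human point estimate;
it is configurable and all closed-form checks scale with it.

Against closed forms, neutral runs reproduce Watterson's E[S] and E[pi]
within ~1–2% and mean Tajima's D within 0.02 of zero (the test suite
asserts 5% and 0.1 over 500 replicates of a 50 kb, n = 20 design — sizes
chosen so the whole check runs in seconds).

**Recombination hotspots** are handled by the extension construction:
intervals above 5 cM/Mb are replaced by baseline-rate stretches inflated
by rate/baseline so total genetic length is conserved; the inserted excess
contributes recombination but is masked for mutations, and surviving
coordinates are projected back. The focal site defaults to the midpoint of
the 185 kb frame (the centre of the 65 kb high-differentiation section);
its exact placement within the frame is a reporting convention and is
configurable.

# ABC inference

For each (non-excluded) simulation a 14-statistic summary vector is
computed: XP-EHH at the focal site over the whole region; Tajima's D and
Fay & Wu's H per deme for the central 65 kb and the combined 120 kb
flanks; mean per-site F_ST per section; the focal derived allele frequency
in both demes; and the focal-site F_ST. Records with test-deme focal DAF
at or below 5% are excluded — identically for simulations and
observations — mirroring the frequency condition under which XP-EHH is
defined. Because this filter (like trajectory-survival rejection) is
model-dependent, the realized prior after filtering is reported alongside
the tables.

Each statistic is shifted positive, Box-Cox transformed (profile-ML
lambda), standardized, and projected onto the first five PLS components of
a regression of model parameters on statistics, pooled across models with
absent parameters coded 0 (the per-component held-out RMSE curves from
`rmse_per_component()` justify five components). Rejection keeps the
nearest simulations by Euclidean distance in PLS space — the retained
fraction defaults to 0.1% of the table, the published acceptance rate.
Posterior model probabilities are retained-count proportions corrected for
unequal simulation effort per model (equal model priors); the Bayes factor
is PP/(1−PP), the identity the published per-population table satisfies.
Parameter posteriors are unweighted quantiles of the retained parameter
values. Cross-validation power draws pseudo-observations from the
reference tables (excluding each from the reference when scored) and
reports per-model correct-assignment fractions and TP/FP/FN counts.

# Synthetic data

The generators exist so every stage is testable without external
downloads; their defaults encode the study conditions. The clinal panel
draws population frequencies as inv-logit(base + beta_lat·z(lat) +
beta_temp·z(temp)) perturbed by Balding–Nichols drift (Beta with parameter
F), and genotypes as Binomial(2, p); Balding–Nichols was chosen because F
maps analytically onto expected F_ST, giving closed-form oracles.
Temperature defaults to a noisy decreasing function of latitude
(27 − 0.35·lat ± 2 °C, an ordinary environmental lapse), reproducing the
collinearity the model set must disentangle. Background SNPs share the
drift model, so empirical P-values are calibrated (uniform under the
null). Ancient samples are Binomial(2, trajectory(age)) with uniform ages
and latitudes; the prevalence generator is linear in DAF with Gaussian
noise clipped to [0, 1].

What the generators deliberately do not emulate: genome-wide linkage
disequilibrium (background SNPs are unlinked frequencies; linked
haplotypes come only from the locus simulator), ascertainment bias, and
sequencing error. Passing tests therefore demonstrate correctness of the
estimators under the stated models, not robustness to those artefacts.

# Numerical choices and degenerate inputs

* Monomorphic sites: F_ST components undefined (flagged, never silently
  0); Tajima's D undefined at S = 0; EHH needs ≥ 2 carriers.
* NJ branch lengths clamped at 0 with the deficit moved to the sister
  branch; midpoint rooting of a two-leaf tree splits the single path.
* Aliased PGLS predictors (e.g. all-zero columns) get NA coefficients,
  lm-style, leaving the likelihood unchanged.
* Rejection ties in ABC are broken by simulation index, making runs
  deterministic given seeds end to end.
* The recombinant-haplotype filter (median pairwise difference > 10,
  calibrated to a ~65 kb window) is a heuristic whose
  scale tracks the window's expected diversity; analyses of other windows
  should rescale it (the tests use a threshold proportional to theta).

# Problem sizes used by the test suite

The packaged checks run the full machinery at reduced scale, chosen as the
smallest sizes at which the published contrasts are expected to be
resolvable: ABC reference tables of 2,000 simulations per primary model
(plus 1,000 for the halted SSV variant) with 200 pseudo-observations per
model at the 0.1% acceptance fraction; 500 neutral replicates for the
closed-form oracles; 50 replicate panels for GLMM coverage; 50
pseudo-observations for ABC parameter coverage. Full-scale analyses of
this design use on the order of 10^6 simulations per selection model; a
full-scale rerun is a matter of the same calls with larger `n_sims`.

# Known limitations

* Balding–Nichols drift perturbs population frequencies on the
  probability scale while the GLMM models population effects on the logit
  scale. Because the logit is convex above 0.5 and concave below, the
  perturbation slightly expands the logit range and inflates the fitted
  cline slope (by roughly 4% at drift F = 0.02 in the packaged coverage
  check), so nominal-95% intervals cover the generating slope a little
  below nominal on synthetic panels. This is a property of the
  generating model, shared by any real data whose drift acts
  multiplicatively on frequencies.
* At desk-scale reference-table sizes the 0.1% acceptance fraction
  retains only a handful of simulations per model choice, so the
  cross-validated assignment fractions carry a few percentage points of
  nearest-neighbour noise; in the packaged runs the hard-sweep model is
  the one that loses the most discriminability relative to a
  full-scale table.

* The SSV pre-onset standing frequency is mirrored between demes rather
  than co-drifted; the published description does not resolve how the
  standing allele was seeded across demes, and the supplementary RMSE
  labels suggest per-deme frequencies existed in some variant of the
  analysis. The mirror is the simpler reading and is isolated in one
  place in the trajectory code.
* The GLMM uses one-dimensional ancestry control (F_ST to the reference);
  residual structure beyond that is absorbed by the population random
  effect, not modelled spatially.
* iHS empirical P-values can be one-sided on −iHS or two-sided on |iHS|;
  both are available, with two-sided the default, since the published
  tables do not disambiguate.
* Bayes factors are computed against the complement of the best model
  (PP/(1−PP)); the alternative convention (best vs best-alternative)
  gives larger values when more than two models carry mass.
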