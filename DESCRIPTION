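Package: clineselect
Title: Selection Scans, Cline Regressions and ABC Inference for
    Latitude-Clinal Local Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise latitude-clinal local adaptation at a
    candidate SNP: Weir-Cockerham FST (per site and genome-wide ratio of
    averages), haplotype-based selection scans (EHH, iHS, XP-EHH) with
    empirical P-values, phylogenetic generalized least squares and binomial
    mixed-model allele-frequency clines with AIC-based multi-model
    inference, recombinant-haplotype filtering for allele-origin inference,
    and an approximate Bayesian computation framework that discriminates
    selection on de novo mutations, selection on standing variation and
    neutrality using a trajectory-conditioned coalescent simulator under an
    out-of-Africa demography. Includes synthetic-data generators so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    lme4,
    MASS,
    vcfR,
    mixOmics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
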