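#' Published per-population scan tables as packaged fixtures
#'
#' Returns transcriptions of the published overview of populations and
#' selection signatures at the focal SNP (per-population latitude,
#' temperature, derived allele frequency, F_ST to the Yoruba reference and
#' empirical P-values), the AIC columns of the PGLS/GLMM multi-model
#' comparisons, and the ABC Bayes-factor / posterior table for the
#' standing-variation model. These serve as regression fixtures: the
#' package's own estimators are checked against them.
#'
#' @return List with elements `populations` (data.frame), `aic` (named list
#'   of data.frames with model/aic/k), and `abc_ssv` (data.frame with
#'   Bayes factors, posterior probabilities and parameter posteriors).
#' @export
table1_fixture <- function() {
  populations <- data.frame(
    population = c("FIN", "GBR", "CEU", "TSI", "IBS", "CHB", "JPT", "PJL",
                   "BEB", "GIH", "CHS", "CDX", "ITU", "GWD", "KHV", "ESN",
                   "STU", "MSL", "YRI", "LWK"),
    continent = c("EUR", "EUR", "EUR", "EUR", "EUR", "EAS", "EAS", "SAS",
                  "SAS", "SAS", "EAS", "EAS", "SAS", "AFR", "EAS", "AFR",
                  "SAS", "AFR", "AFR", "AFR"),
    latitude = c(60.25, 54.75, 50.75, 43.25, 40.25, 39.75, 35.25, 31.25,
                 23.25, 23.25, 22.25, 22.25, 16.75, 13.25, 10.25, 6.75,
                 9.25, 7.75, 7.25, 0.75),
    longitude = c(24.75, -1.25, 4.25, 11.25, -3.25, 116.25, 139.25, 74.25,
                  90.25, 72.75, 114.25, 100.25, 80.75, -16.25, 106.25, 6.25,
                  80.25, -11.25, 3.75, 34.75),
    temperature = c(5.7, 10.0, 10.7, 14.2, 14.9, 13.4, 14.8, 25.3, 26.1,
                    27.7, 23.4, 19.2, 28.6, 27.2, 28.2, 27.0, 28.5, 26.6,
                    27.6, 20.5),
    daf = c(0.87, 0.80, 0.82, 0.84, 0.80, 0.39, 0.45, 0.57, 0.52, 0.53,
            0.36, 0.30, 0.39, 0.06, 0.30, 0.04, 0.37, 0.03, 0.05, 0.07),
    fst = c(0.805, 0.724, 0.751, 0.778, 0.733, 0.279, 0.349, 0.472, 0.428,
            0.437, 0.254, 0.184, 0.278, -0.007, 0.193, -0.007, 0.262,
            -0.005, NA, -0.002),
    fst_pvalue = c(2e-04, 6e-04, 4e-04, 2e-04, 4e-04, 0.055, 0.0356,
                   0.0066, 0.0102, 0.0101, 0.0666, 0.1051, 0.0367, 0.861,
                   0.0953, 0.8046, 0.0411, 0.6836, NA, 0.6912),
    xpehh_pvalue = c(0.205, 0.287, 0.228, 0.26, 0.291, 0.939, 0.947, 0.651,
                     0.605, 0.587, 0.927, 0.895, 0.804, NA, 0.938, NA,
                     0.866, NA, NA, NA),
    ihs_pvalue = c(0.166, 0.304, 0.36, 0.622, 0.656, 0.219, 0.593, 0.869,
                   0.8, 0.821, 0.161, 0.926, 0.952, 0.39, 0.69, NA, 0.626,
                   NA, 0.699, 0.901),
    stringsAsFactors = FALSE)

  models <- c("Null+Lat.", "Null+Temp.+Lat.", "Null+Temp.", "Null")
  aic <- list(
    pgls_1kgp = data.frame(
      model = c("Null+Lat.", "Null+Temp.+Lat.", "Null+Temp.", "Null"),
      aic = c(-49.43, -49.186, -44.147, -42.255), k = c(5, 6, 5, 4),
      stringsAsFactors = FALSE),
    glmm_1kgp = data.frame(
      model = c("Null+Temp.+Lat.", "Null+Lat.", "Null+Temp.", "Null"),
      aic = 1929.2 + c(0, 0.09, 10.633, 16.964), k = c(6, 5, 5, 4),
      stringsAsFactors = FALSE),
    glmm_sgdp = data.frame(
      model = c("Null+Temp.+Lat.", "Null+Lat.", "Null+Temp.", "Null"),
      aic = c(435.206, 440.841, 451.699, 452.458), k = c(6, 5, 5, 4),
      stringsAsFactors = FALSE),
    glmm_sgdp_eurasia = data.frame(
      model = c("Null+Lat.", "Null+Temp.+Lat.", "Null+Temp.", "Null"),
      aic = c(301.301, 302.35, 305.874, 308.611), k = c(5, 6, 5, 4),
      stringsAsFactors = FALSE))

  abc_ssv <- data.frame(
    population = c("FIN", "GBR", "CEU", "TSI", "IBS", "CHB", "JPT", "PJL",
                   "BEB", "GIH", "CHS", "CDX", "ITU", "KHV", "STU"),
    bayes_factor = c(9.6, 588.3, 474.8, 23.3, 17.5, 81.8, 25.8, 70, 7.4,
                     17.4, 220.9, 4.6, 10.6, 3.1, 14.4),
    posterior_prob = c(0.906, 0.998, 0.998, 0.959, 0.946, 0.988, 0.963,
                       0.986, 0.882, 0.946, 0.996, 0.823, 0.914, 0.755,
                       0.935),
    t0_median = c(35055, 29783, 31390, 36789, 32558, 24529, 25509, 25017,
                  26887, 26298, 24407, 26438, 26297, 26399, 26024),
    t0_q025 = c(22052, 21384, 21311, 22088, 21520, 21067, 21103, 21101,
                21118, 21122, 21047, 21088, 21100, 21110, 21097),
    t0_q975 = c(49881, 49231, 49593, 50000, 49666, 47771, 48685, 48055,
                48393, 48234, 47586, 47862, 48424, 48452, 48491),
    s_na_median = c(1.238, 1.352, 1.453, 1.418, 1.209, 0.270, 0.269, 0.378,
                    0.293, 0.314, 0.271, 0.234, 0.249, 0.204, 0.249),
    f_sel_median = c(0.078, 0.075, 0.080, 0.111, 0.090, 0.081, 0.080,
                     0.077, 0.082, 0.079, 0.079, 0.075, 0.073, 0.075,
                     0.071),
    stringsAsFactors = FALSE)

  list(populations = populations, aic = aic, abc_ssv = abc_ssv)
}
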