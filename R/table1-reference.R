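#' Reference statistics for the 13 alcohol-responsive organic acids
#'
#' Published per-time mean concentrations (umol/mmol creatinine), standard
#' deviations, PLS-DA VIP at the 0 vs 1 h contrast, Wilcoxon signed-rank
#' p-values and signed fold changes for the 13 urinary organic acids most
#' perturbed one hour after an acute alcohol intervention in 12 healthy young
#' men. Used as annotation, as the anchor profiles of [table1_preset()], and
#' as printed-table input for recomputing fold changes.
#'
#' @return Tibble with one row per metabolite: `metabolite`, `vip`, `p_0_1`,
#'   `fc_0_1`, `p_0_4`, `fc_0_4`, `mean_0` .. `mean_4`, `sd_0` .. `sd_4`.
#' @export
table1_reference <- function() {
  tibble::tribble(
    ~metabolite, ~vip, ~p_0_1, ~fc_0_1, ~p_0_4, ~fc_0_4,
    ~mean_0, ~mean_1, ~mean_2, ~mean_3, ~mean_4,
    ~sd_0, ~sd_1, ~sd_2, ~sd_3, ~sd_4,
    "hippuric_acid",           19.6, 0.002,  3.2, 0.239, -1.3, 948, 3037, 2775, 1157, 726, 737, 1357, 2051, 1111, 764,
    "lactic_acid",             14.4, 0.015, 27.4, 0.209,  1.4, 8.73, 239, 28.1, 15.5, 12.1, 3.65, 412, 19.7, 14.7, 8.51,
    "fumaric_acid",            7.24, 0.003,  6.4, 0.006,  3.6, 0.78, 4.96, 5.88, 2.62, 2.8, 0.47, 4.53, 6.08, 1.94, 2.15,
    "vanillylmandelic_acid",   5.03, 0.034, -1.6, 0.002, -8.8, 15.4, 9.87, 2.96, 1.87, 1.75, 3.61, 7.39, 2.32, 1.11, 0.99,
    "x2_hydroxybutyric_acid",  4.06, 0.034,  4.3, 0.695, -1.1, 2.68, 11.4, 3.85, 2.26, 2.52, 1.54, 16.0, 2.68, 1.16, 2.15,
    "succinic_acid",           3.88, 0.010,  2.6, 0.004,  3.3, 3.81, 9.83, 20.2, 12.8, 12.7, 3.81, 7.90, 24.6, 12.8, 12.3,
    "x3_hydroxybutyric_acid",  2.76, 0.041,  5.9, 0.182,  1.9, 0.40, 2.39, 0.59, 0.47, 0.77, 0.54, 2.96, 0.55, 0.40, 0.68,
    "x2_ethylhydracrylic_acid",1.66, 0.010,  2.1, 0.015,  1.7, 1.09, 2.30, 2.53, 1.76, 1.86, 1.00, 1.73, 2.78, 1.61, 1.47,
    "x3_hydroxyisobutyric_acid",1.56,0.034,  1.9, 0.239,  1.1, 3.01, 5.76, 3.31, 2.74, 3.44, 1.27, 3.86, 2.05, 1.25, 1.95,
    "x2_hydroxyisobutyric_acid",1.39,0.034,  1.8, 0.209,  1.5, 11.1, 20.5, 20.5, 12.8, 16.3, 4.03, 14.2, 13.4, 6.93, 13.1,
    "malic_acid",              1.32, 0.023,  4.9, 0.006,  4.5, 0.27, 1.30, 1.81, 0.86, 1.19, 0.16, 1.60, 1.59, 0.67, 1.37,
    "n_tiglylglycine",         1.22, 0.034,  1.7, 0.002,  7.0, 1.55, 2.65, 10.9, 10.9, 10.8, 1.15, 1.39, 9.15, 9.35, 8.64,
    "x2_hydroxyglutaric_acid", 1.06, 0.023,  1.7, 0.003,  3.0, 2.88, 4.91, 10.0, 7.22, 8.50, 0.99, 3.39, 5.90, 3.62, 5.73
  )
}
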