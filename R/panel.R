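#' Published ITC thermodynamics of bromosporine against human bromodomains
#'
#' The reference panel of reverse-titration ITC results for the
#' pan-bromodomain chemical probe bromosporine (BSP): per-protein syringe and
#' cell concentrations, dissociation constant, observed binding enthalpy,
#' stoichiometry (each with fit SD), and the derived entropic and free-energy
#' terms, all at 15 degrees C. Rows where no reliable single-site fit could
#' be obtained carry `weak_binding = TRUE` and `NA` numeric columns. Used as
#' a thermodynamic consistency reference, as preset concentrations for the
#' synthetic titration generator, and for table rendering.
#'
#' @return tibble with columns `protein`, `p_uM` (syringe protein, uM),
#'   `l_uM` (cell ligand, uM), `kd_nM`, `kd_sd`, `dh`, `dh_sd`, `n`, `n_sd`,
#'   `tds`, `dg` (kcal/mol), `weak_binding`
#' @export
#' @examples
#' panel <- bsp_itc_panel()
#' subset(panel, protein == "BRD4(1)")
bsp_itc_panel <- function() {
  tibble::tribble(
    ~protein,    ~p_uM, ~l_uM, ~kd_nM, ~kd_sd, ~dh,    ~dh_sd, ~n,   ~n_sd,  ~tds,  ~dg,
    "BAZ2A",     433,   15,    3745,   291,    -3.04,  0.095,  1.05, 0.025,  4.12,  -7.16,
    "BAZ2B",     607,   15,    NA,     NA,     NA,     NA,     NA,   NA,     NA,    NA,
    "BRD1",      440,   13,    1653,   66,     -7.32,  0.078,  1.01, 0.008,  0.30,  -7.62,
    "BRD2(1)",   271,   25,    97.1,   6.7,    -7.90,  0.034,  1.00, 0.003,  1.34,  -9.25,
    "BRD2(2)",   235,   25,    50.3,   5.0,    -5.46,  0.028,  1.10, 0.003,  4.18,  -9.64,
    "BRD3(1)",   275,   20,    91.7,   5.3,    -10.02, 0.039,  1.00, 0.002,  -0.95, -9.08,
    "BRD3(2)",   305,   25,    50.0,   4.7,    -8.62,  0.041,  1.11, 0.003,  1.01,  -9.63,
    "BRD4(1)",   258,   20,    41.8,   2.8,    -11.09, 0.038,  0.94, 0.002,  -1.36, -9.73,
    "BRD4(2)",   270,   20,    39.7,   2.2,    -6.60,  0.018,  0.94, 0.001,  3.17,  -9.77,
    "BRDT(1)",   228,   20,    40.2,   2.8,    -13.16, 0.047,  1.02, 0.002,  -3.40, -9.76,
    "BRDT(2)",   271,   20,    172.1,  10.6,   -5.61,  0.028,  1.00, 0.003,  3.31,  -8.92,
    "BRD9",      251,   25,    41.7,   3.8,    -8.75,  0.039,  1.00, 0.002,  0.98,  -9.73,
    "BRPF1B",    406,   20,    311.5,  11.2,   -6.12,  0.021,  1.00, 0.003,  2.45,  -8.57,
    "BRPF3",     400,   15,    8621,   381,    -4.20,  0.123,  1.08, 0.025,  2.48,  -6.68,
    "CECR2",     202,   16,    8.0,    1.0,    -17.28, 0.062,  1.04, 0.002,  -6.60, -10.68,
    "CREBBP",    617,   25,    1524,   116,    -2.91,  0.041,  1.03, 0.011,  4.72,  -7.64,
    "EP300",     460,   15,    7194,   501,    -5.65,  0.265,  0.97, 0.036,  1.13,  -6.78,
    "BPTF",      230,   15,    1887,   53,     -10.09, 0.074,  1.07, 0.005,  -3.28, -6.80,
    "GCN5L2",    336,   15,    NA,     NA,     NA,     NA,     NA,   NA,     NA,    NA,
    "PB1(3)",    389,   15,    NA,     NA,     NA,     NA,     NA,   NA,     NA,    NA,
    "PB1(5)",    604,   15,    14225,  802,    -3.19,  0.183,  1.09, 0.053,  3.20,  -6.39,
    "PCAF",      610,   13,    4762,   459,    -7.85,  0.454,  0.95, 0.044,  -0.83, -7.02,
    "SMARCA2",   222,   25,    NA,     NA,     NA,     NA,     NA,   NA,     NA,    NA,
    "SMARCA4",   400,   13,    19685,  838,    -9.05,  0.580,  0.99, 0.055,  -2.84, -6.21,
    "TAF1(1)",   460,   23,    5525,   199,    -3.34,  0.046,  0.98, 0.010,  3.60,  -6.94,
    "TAF1(2)",   230,   20,    16.6,   2.7,    -14.05, 0.095,  0.98, 0.003,  -3.80, -10.25,
    "TAF1L(1)",  610,   13,    25000,  2027,   -4.78,  0.778,  1.00, 0.146,  1.29,  -6.07,
    "TAF1L(2)",  250,   20,    42.7,   4.4,    -12.48, 0.069,  0.99, 0.003,  -2.76, -9.72,
    "TIF1A",     400,   15,    8475,   431,    -2.61,  0.088,  1.09, 0.029,  4.06,  -6.67
  ) |>
    dplyr::mutate(weak_binding = is.na(kd_nM))
}

#' Published thermal-shift panel for the biotinylated probe variants
#'
#' Mean +/- SD melting-temperature shifts (degrees C, triplicate) of the two
#' biotinylated bromosporine variants (BSP-a, BSP-b) against a panel of 12
#' bromodomains, at 10 uM compound and 2 uM protein. Serves as the design
#' template (12 proteins x 2 compounds x triplicate) for the synthetic melt
#' plate generator.
#'
#' @return tibble with columns `protein`, `compound`, `delta_tm_mean_C`,
#'   `delta_tm_sd_C`
#' @export
bsp_dtm_panel <- function() {
  a <- tibble::tribble(
    ~protein,   ~bsp_a, ~sd_a, ~bsp_b, ~sd_b,
    "BRD2(1)",  -7.5,   0.7,   1.9,    0.5,
    "BRD2(2)",  -0.4,   0.2,   3.0,    0.2,
    "BRD3(1)",  -2.7,   0.2,   2.3,    0.3,
    "BRD3(2)",  -3.0,   0.1,   3.1,    0.0,
    "BRD4(1)",  -2.7,   0.2,   3.8,    0.3,
    "BRD4(2)",  -5.1,   0.0,   1.8,    0.3,
    "BRDT(1)",  -5.0,   0.1,   1.3,    0.3,
    "BRDT(2)",  0.5,    0.1,   0.9,    0.4,
    "CECR2",    4.3,    0.0,   7.4,    0.1,
    "CREBBP",   -3.1,   0.6,   0.1,    0.4,
    "TAF1(2)",  -12.4,  0.1,   1.9,    0.1,
    "TAF1L(2)", 0.2,    0.1,   2.9,    0.4
  )
  dplyr::bind_rows(
    tibble::tibble(protein = a$protein, compound = "BSP-a",
                   delta_tm_mean_C = a$bsp_a, delta_tm_sd_C = a$sd_a),
    tibble::tibble(protein = a$protein, compound = "BSP-b",
                   delta_tm_mean_C = a$bsp_b, delta_tm_sd_C = a$sd_b)
  )
}
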