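#' Synthetic melt plate with known truth
#'
#' Simulates per-well two-state melt curves from [eval_melt_model()] plus
#' i.i.d. Gaussian noise on the default instrument ramp (25-96 degrees C).
#' Replicate wells share generating parameters and differ only by noise.
#'
#' @param plate_spec tibble with one row per well: `well`, `protein`,
#'   `compound` (`NA` = reference), `conc_uM`, `tm`, `dh_unfold`,
#'   `yf_int`, `yf_slope`, `yu_int`, `yu_slope`
#' @param noise_sd Gaussian noise SD in AU (default 1% of a 1000-5000 AU
#'   span)
#' @param seed integer seed; each well draws from its own child stream
#' @param temp_grid temperatures in degrees C (default 25-96 by 0.5)
#' @return list with `curves` (list of [melt_curve()]) and `truth`
#'   (a `synthetic_truth` list)
#' @export
gen_melt_plate <- function(plate_spec, noise_sd = 40, seed = 1L,
                           temp_grid = seq(25, 96, by = 0.5)) {
  curves <- vector("list", nrow(plate_spec))
  for (i in seq_len(nrow(plate_spec))) {
    w <- plate_spec[i, ]
    y <- eval_melt_model(temp_grid, w$tm, w$dh_unfold,
                         native_baseline = c(w$yf_int, w$yf_slope),
                         denatured_baseline = c(w$yu_int, w$yu_slope))
    if (noise_sd > 0) {
      set.seed(child_seed(seed, i))
      y <- y + rnorm(length(y), sd = noise_sd)
    }
    curves[[i]] <- melt_curve(w$well, temp_grid, y,
                              protein_id = w$protein,
                              compound_id = w$compound,
                              compound_conc = w$conc_uM)
  }
  truth <- synthetic_truth("dsf", as.list(plate_spec),
                           noise = list(distribution = "gaussian", sd = noise_sd),
                           seed = seed)
  list(curves = curves, truth = truth)
}

#' Default plate layout emulating the published thermal-shift panel design
#'
#' Twelve proteins by two compounds in triplicate, plus triplicate reference
#' wells per protein, with the per-(protein, compound) true shifts taken from
#' [bsp_dtm_panel()] applied to a common reference midpoint.
#'
#' @param tm_ref reference (apo) melting temperature in degrees C
#' @param dh_unfold unfolding enthalpy used for every well
#' @return plate-spec tibble for [gen_melt_plate()]
#' @export
dtm_panel_plate_spec <- function(tm_ref = 50, dh_unfold = 120) {
  panel <- bsp_dtm_panel()
  proteins <- unique(panel$protein)
  rows <- list()
  well_i <- 0L
  add_well <- function(protein, compound, conc, tm) {
    well_i <<- well_i + 1L
    tibble::tibble(
      well = sprintf("W%03d", well_i), protein = protein,
      compound = compound, conc_uM = conc, tm = tm,
      dh_unfold = dh_unfold, yf_int = 1000, yf_slope = -2,
      yu_int = 5000, yu_slope = -5
    )
  }
  for (p in proteins) {
    for (r in 1:3) rows[[length(rows) + 1L]] <- add_well(p, NA_character_, NA_real_, tm_ref)
    for (cmp in c("BSP-a", "BSP-b")) {
      shift <- panel$delta_tm_mean_C[panel$protein == p & panel$compound == cmp]
      for (r in 1:3) rows[[length(rows) + 1L]] <- add_well(p, cmp, 10, tm_ref + shift)
    }
  }
  dplyr::bind_rows(rows)
}

#' Synthetic single-site ITC titration
#'
#' Heats from [simulate_injection_heats()] under the standard reverse
#' schedule (0.3 ul control + 38 x 1 ul into 0.2003 ml at 15 degrees C),
#' plus a volume-proportional dilution offset and Gaussian noise.
#'
#' @param n,kd,dh true stoichiometry, dissociation constant (nM) and
#'   enthalpy (kcal/mol)
#' @param syringe_conc,cell_conc concentrations in uM
#' @param dilution_offset dilution heat in ucal per ul injected
#' @param noise_sd Gaussian noise SD in ucal
#' @param seed integer seed
#' @param injection_volumes schedule in ul (control first)
#' @param cell_volume ml
#' @param temperature degrees C
#' @param protein_id,compound_id identifiers
#' @return list with `titration` and `truth`
#' @export
gen_titration <- function(n = 1, kd = 41.8, dh = -11.09,
                          syringe_conc = 258, cell_conc = 20,
                          dilution_offset = 0.5, noise_sd = 0.1, seed = 1L,
                          injection_volumes = c(0.3, rep(1, 38)),
                          cell_volume = 0.2003, temperature = 15,
                          protein_id = "protein", compound_id = "compound") {
  titr <- titration(syringe_conc, cell_conc,
                    heats = rep(0, length(injection_volumes)),
                    injection_volumes = injection_volumes,
                    cell_volume = cell_volume, temperature = temperature,
                    protein_id = protein_id, compound_id = compound_id)
  heats <- simulate_injection_heats(titr, n, kd, dh) +
    dilution_offset * injection_volumes
  if (noise_sd > 0) {
    set.seed(child_seed(seed, 0L))
    heats <- heats + rnorm(length(heats), sd = noise_sd)
  }
  titr$heats <- heats
  truth <- synthetic_truth(
    "itc",
    list(n = n, kd = kd, dh = dh, syringe_conc = syringe_conc,
         cell_conc = cell_conc, dilution_offset = dilution_offset,
         cell_volume = cell_volume, temperature = temperature),
    noise = list(distribution = "gaussian", sd = noise_sd), seed = seed
  )
  list(titration = titr, truth = truth)
}

#' Preset titration parameters from the published panel
#'
#' Concentration pairs and fitted parameters for a named panel protein,
#' usable directly as `gen_titration()` arguments.
#'
#' @param protein protein name as in [bsp_itc_panel()], e.g. `"BRD4(1)"`
#' @return named list: `n`, `kd`, `dh`, `syringe_conc`, `cell_conc`,
#'   `protein_id`
#' @export
itc_preset <- function(protein = "BRD4(1)") {
  panel <- bsp_itc_panel()
  row <- panel[panel$protein == protein, ]
  if (nrow(row) == 0) abort_pt("unknown panel protein '", protein, "'")
  if (row$weak_binding) abort_pt("'", protein, "' is a weak-binding panel row")
  list(n = row$n, kd = row$kd_nM, dh = row$dh,
       syringe_conc = row$p_uM, cell_conc = row$l_uM, protein_id = protein)
}

#' Synthetic FRAP traces
#'
#' Per-cell three-channel traces with a prebleach plateau, a bleach drop and
#' single-exponential recovery with an immobile fraction. A linear
#' multiplicative acquisition drift is applied jointly to the ROI and
#' whole-nucleus channels (the double normalization must cancel it), then
#' Gaussian noise is added per channel.
#'
#' @param k recovery rate in 1/s
#' @param mobile mobile fraction in (0, 1]
#' @param bleach_depth fraction of ROI signal removed by the bleach, (0, 1]
#' @param n_cells number of cells (traces)
#' @param noise_sd Gaussian noise SD on the normalized-intensity scale
#' @param drift total fractional linear acquisition drift across the series
#'   (e.g. 0.1 = 10% loss by the last frame)
#' @param dt frame interval in s
#' @param n_prebleach prebleach prescans
#' @param n_post post-bleach frames
#' @param i_pre,t_pre,bg true prebleach ROI/nucleus/background levels (AU)
#' @param seed integer seed; one child stream per cell
#' @param treatment,concentration metadata attached to every trace
#' @return list with `traces` (list of [frap_trace()]) and `truth`
#' @export
gen_frap_traces <- function(k = 1, mobile = 0.9, bleach_depth = 0.6,
                            n_cells = 30, noise_sd = 0.03, drift = 0,
                            dt = 0.25, n_prebleach = 5, n_post = 80,
                            i_pre = 1000, t_pre = 5000, bg = 50, seed = 1L,
                            treatment = NA_character_,
                            concentration = NA_real_) {
  if (mobile <= 0 || mobile > 1) abort_pt("mobile must be in (0, 1]")
  if (bleach_depth <= 0 || bleach_depth > 1) abort_pt("bleach_depth must be in (0, 1]")
  n_frames <- n_prebleach + n_post
  times <- (seq_len(n_frames) - 1) * dt
  bleach_frame <- n_prebleach + 1L
  t_post_rel <- times[bleach_frame:n_frames] - times[bleach_frame]
  rel_true <- c(rep(1, n_prebleach),
                (1 - bleach_depth) +
                  bleach_depth * mobile * (1 - exp(-k * t_post_rel)))
  roi_frac <- i_pre / t_pre
  t_true <- c(rep(1, n_prebleach),
              rep(1 - bleach_depth * roi_frac, n_post)) # nucleus loses the bleached pool
  drift_fac <- 1 - drift * (seq_len(n_frames) - 1) / max(n_frames - 1, 1)
  traces <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    set.seed(child_seed(seed, cell))
    i_sig <- rel_true * i_pre * t_true
    t_sig <- t_pre * t_true
    if (noise_sd > 0) {
      i_sig <- i_sig + rnorm(n_frames, sd = noise_sd * i_pre)
      t_sig <- t_sig + rnorm(n_frames, sd = noise_sd * t_pre)
    }
    # acquisition gain drift multiplies everything detected above background
    i_sig <- i_sig * drift_fac
    t_sig <- t_sig * drift_fac
    traces[[cell]] <- frap_trace(times, i_sig + bg, t_sig + bg, bg,
                                 bleach_frame = bleach_frame,
                                 n_prebleach = n_prebleach,
                                 cell_id = sprintf("cell%03d", cell),
                                 treatment = treatment,
                                 concentration = concentration)
  }
  truth <- synthetic_truth(
    "frap",
    list(k = k, t_half = log(2) / k, mobile = mobile,
         bleach_depth = bleach_depth, dt = dt, n_prebleach = n_prebleach,
         n_post = n_post, drift = drift, n_cells = n_cells),
    noise = list(distribution = "gaussian", sd = noise_sd), seed = seed
  )
  list(traces = traces, truth = truth)
}

# internal: single-agent fraction affected under the median-effect (Hill) model
me_fa <- function(dose, dm, m) {
  ifelse(dose <= 0, 0, 1 / (1 + (dm / dose)^m))
}

# internal: Loewe-additive fa of a combination (d1, d2) by bisection on fa
loewe_fa <- function(d1, d2, dm1, m1, dm2, m2) {
  if (d1 <= 0 && d2 <= 0) return(0)
  g <- function(fa) {
    dx1 <- dm1 * (fa / (1 - fa))^(1 / m1)
    dx2 <- dm2 * (fa / (1 - fa))^(1 / m2)
    d1 / dx1 + d2 / dx2 - 1
  }
  uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

#' Synthetic viability checkerboard
#'
#' Single-agent rows/columns follow each drug's median-effect model;
#' combination wells follow the chosen interaction rule: `"loewe"` (dose
#' additivity, CI = 1 by construction), `"bliss"` (response-multiplicative
#' independence), or `"sham"` (drug B is drug A in disguise, each well
#' receiving total dose d1 + d2 under drug A's model -- the classical
#' self-combination control). Gaussian noise is added on the fa scale and
#' clipped to [0, 1].
#'
#' @param dm_a,dm_b median-effect doses in nM
#' @param m_a,m_b sigmoidicity (Hill) exponents
#' @param interaction `"loewe"`, `"bliss"` or `"sham"`
#' @param doses_a,doses_b dose levels in nM including 0; defaults are
#'   eight-point geometric series spanning the published combination ranges
#'   (0.7-11392 nM, a near-fourfold series, and 37-4728 nM, near-twofold)
#' @param noise_sd Gaussian noise SD on the fa scale
#' @param seed integer seed
#' @return list with `grid` (a [dose_grid()]) and `truth`
#' @export
gen_dose_grid <- function(dm_a = 200, dm_b = 1000, m_a = 1, m_b = 1,
                          interaction = c("loewe", "bliss", "sham"),
                          doses_a = c(0, exp(seq(log(0.7), log(11392), length.out = 8))),
                          doses_b = c(0, exp(seq(log(37), log(4728), length.out = 8))),
                          noise_sd = 0, seed = 1L) {
  interaction <- match.arg(interaction)
  fa <- matrix(0, length(doses_a), length(doses_b))
  for (i in seq_along(doses_a)) {
    for (j in seq_along(doses_b)) {
      d1 <- doses_a[i]; d2 <- doses_b[j]
      fa[i, j] <-
        if (d1 == 0 && d2 == 0) 0
        else if (d2 == 0) me_fa(d1, dm_a, m_a)
        else if (d1 == 0) me_fa(d2, dm_b, m_b)
        else switch(interaction,
          loewe = loewe_fa(d1, d2, dm_a, m_a, dm_b, m_b),
          bliss = 1 - (1 - me_fa(d1, dm_a, m_a)) * (1 - me_fa(d2, dm_b, m_b)),
          sham = me_fa(d1 + d2, dm_a, m_a)
        )
    }
  }
  if (noise_sd > 0) {
    set.seed(child_seed(seed, 0L))
    fa <- fa + matrix(rnorm(length(fa), sd = noise_sd), nrow(fa))
    fa <- pmin(pmax(fa, 0), 1)
  }
  grid <- dose_grid(doses_a, doses_b, fa)
  truth <- synthetic_truth(
    "dose",
    list(dm_a = dm_a, dm_b = dm_b, m_a = m_a, m_b = m_b,
         interaction = interaction, doses_a = doses_a, doses_b = doses_b),
    noise = list(distribution = "gaussian", sd = noise_sd), seed = seed
  )
  list(grid = grid, truth = truth)
}

#' Ground-truth record attached to every synthetic dataset
#'
#' @param modality one of `"dsf"`, `"itc"`, `"frap"`, `"dose"`
#' @param parameters generating parameters (modality-specific list)
#' @param noise noise model description (list: distribution, sd)
#' @param seed the seed the dataset was generated with
#' @return list of class `synthetic_truth`
#' @export
synthetic_truth <- function(modality, parameters, noise, seed) {
  structure(list(modality = modality, parameters = parameters,
                 noise = noise, seed = seed),
            class = "synthetic_truth")
}

#' Write / read a ground-truth record as JSON
#' @param truth a [synthetic_truth()]
#' @param path JSON file path
#' @return `path` (write) or the `synthetic_truth` (read)
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(x$modality, x$parameters, x$noise, x$seed)
}
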