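#' Read melt curves from a long-format CSV
#'
#' Columns `well,protein,compound,conc_uM,temperature_C,fluorescence`; an
#' empty `compound` marks a reference well.
#'
#' @param path CSV path
#' @return list of [melt_curve()]
#' @export
read_melt_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          well = readr::col_character(),
                          protein = readr::col_character(),
                          compound = readr::col_character(),
                          conc_uM = readr::col_double(),
                          temperature_C = readr::col_double(),
                          fluorescence = readr::col_double()))
  need <- c("well", "protein", "compound", "conc_uM", "temperature_C", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_pt("melt CSV '", path, "' is missing columns: ", paste(miss, collapse = ", "))
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$temperature_C), ]
    cmp <- d$compound[1]
    if (!is.na(cmp) && !nzchar(cmp)) cmp <- NA_character_
    melt_curve(d$well[1], d$temperature_C, d$fluorescence,
               protein_id = d$protein[1], compound_id = cmp,
               compound_conc = d$conc_uM[1])
  })
}

#' Write melt curves to the long-format CSV dialect
#' @param curves list of [melt_curve()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_melt_csv <- function(curves, path) {
  df <- dplyr::bind_rows(lapply(curves, function(cv) {
    tibble::tibble(well = cv$well_id, protein = cv$protein_id,
                   compound = ifelse(is.na(cv$compound_id), "", cv$compound_id),
                   conc_uM = cv$compound_conc,
                   temperature_C = cv$temperatures,
                   fluorescence = cv$fluorescence)
  }))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read melt curves from a wide-format CSV plus a plate map
#'
#' Wide format: first column `temperature_C`, remaining columns one per well;
#' the plate map CSV has columns `well,protein,compound,conc_uM`.
#'
#' @param path wide CSV path
#' @param plate_map_path plate-map CSV path
#' @return list of [melt_curve()]
#' @export
read_melt_wide_csv <- function(path, plate_map_path) {
  wide <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (names(wide)[1] != "temperature_C")
    abort_pt("wide melt CSV must have 'temperature_C' as its first column")
  pm <- readr::read_csv(plate_map_path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(well = readr::col_character(),
                                                protein = readr::col_character(),
                                                compound = readr::col_character(),
                                                conc_uM = readr::col_double()))
  long <- tidyr::pivot_longer(wide, -"temperature_C",
                              names_to = "well", values_to = "fluorescence")
  lapply(split(long, long$well), function(d) {
    row <- pm[pm$well == d$well[1], ]
    if (nrow(row) == 0)
      abort_pt("well '", d$well[1], "' is not in the plate map")
    cmp <- row$compound[1]
    if (!is.na(cmp) && !nzchar(cmp)) cmp <- NA_character_
    d <- d[order(d$temperature_C), ]
    melt_curve(d$well[1], d$temperature_C, d$fluorescence,
               protein_id = row$protein[1], compound_id = cmp,
               compound_conc = row$conc_uM[1])
  })
}

#' Write a delta-Tm summary table as TSV
#' @param summary tibble from [plate_summary()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_dtm_tsv <- function(summary, path) {
  out <- tibble::tibble(protein = summary$protein, compound = summary$compound,
                        delta_tm_mean_C = summary$delta_tm_mean_C,
                        delta_tm_sd_C = summary$delta_tm_sd_C, n = summary$n)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an integrated-heats CSV into a titration
#'
#' Data columns `injection_index,volume_ul,heat_ucal`, preceded by a
#' metadata header block of `# key: value` lines carrying
#' `syringe_conc_uM`, `cell_conc_uM`, `cell_volume_ml`, `temperature_C`,
#' `protein_id`, `compound_id`.
#'
#' @param path CSV path
#' @return a [titration()]
#' @export
read_itc_csv <- function(path) {
  meta <- read_metadata_header(path)
  need <- c("syringe_conc_uM", "cell_conc_uM", "cell_volume_ml", "temperature_C")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    abort_pt("ITC CSV '", path, "' header is missing: ", paste(miss, collapse = ", "))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          injection_index = readr::col_integer(),
                          volume_ul = readr::col_double(),
                          heat_ucal = readr::col_double()))
  df <- df[order(df$injection_index), ]
  titration(meta$syringe_conc_uM, meta$cell_conc_uM, df$heat_ucal,
            injection_volumes = df$volume_ul,
            cell_volume = meta$cell_volume_ml,
            temperature = meta$temperature_C,
            protein_id = if (!is.null(meta$protein_id)) meta$protein_id else "protein",
            compound_id = if (!is.null(meta$compound_id)) meta$compound_id else "compound")
}

#' Write a titration to the integrated-heats CSV dialect
#' @param titr a [titration()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_itc_csv <- function(titr, path) {
  meta <- list(syringe_conc_uM = titr$syringe_conc,
               cell_conc_uM = titr$cell_conc,
               cell_volume_ml = titr$cell_volume,
               temperature_C = titr$temperature,
               protein_id = titr$protein_id,
               compound_id = titr$compound_id)
  df <- tibble::tibble(injection_index = seq_along(titr$heats),
                       volume_ul = titr$injection_volumes,
                       heat_ucal = titr$heats)
  write_csv_with_metadata(df, meta, path)
}

#' Read a FRAP trace CSV
#'
#' Data columns `time_s,I_roi,T_nucleus,BG`, with a `# key: value` header
#' carrying `cell_id`, `treatment`, `concentration`, `bleach_frame`,
#' `n_prebleach`.
#'
#' @param path CSV path
#' @return a [frap_trace()]
#' @export
read_frap_csv <- function(path) {
  meta <- read_metadata_header(path)
  if (is.null(meta$bleach_frame) || is.null(meta$n_prebleach))
    abort_pt("FRAP CSV '", path, "' header needs bleach_frame and n_prebleach")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          I_roi = readr::col_double(),
                          T_nucleus = readr::col_double(),
                          BG = readr::col_double()))
  frap_trace(df$time_s, df$I_roi, df$T_nucleus, df$BG,
             bleach_frame = as.integer(meta$bleach_frame),
             n_prebleach = as.integer(meta$n_prebleach),
             cell_id = if (!is.null(meta$cell_id)) as.character(meta$cell_id) else "cell",
             treatment = if (!is.null(meta$treatment)) as.character(meta$treatment) else NA_character_,
             concentration = if (!is.null(meta$concentration)) meta$concentration else NA_real_)
}

#' Write a FRAP trace to its CSV dialect
#' @param trace a [frap_trace()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frap_csv <- function(trace, path) {
  meta <- list(cell_id = trace$cell_id, treatment = trace$treatment,
               concentration = trace$concentration,
               bleach_frame = trace$bleach_frame,
               n_prebleach = trace$n_prebleach)
  meta <- meta[!vapply(meta, function(v) is.null(v) || all(is.na(v)), logical(1))]
  df <- tibble::tibble(time_s = trace$times, I_roi = trace$bleached_roi,
                       T_nucleus = trace$whole_nucleus, BG = trace$background)
  write_csv_with_metadata(df, meta, path)
}

#' Read a long-format checkerboard viability CSV
#'
#' Columns `drug_a,dose_a_nM,drug_b,dose_b_nM,replicate,od_raw,od_blank`;
#' rows with both doses 0 are the vehicle controls. Raw readings are
#' blank-subtracted, vehicle-normalized with [normalize_viability()] and
#' averaged over replicates into a [dose_grid()] of fractions affected.
#'
#' @param path CSV path
#' @return a [dose_grid()]
#' @export
read_dose_grid_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          drug_a = readr::col_character(),
                          dose_a_nM = readr::col_double(),
                          drug_b = readr::col_character(),
                          dose_b_nM = readr::col_double(),
                          replicate = readr::col_integer(),
                          od_raw = readr::col_double(),
                          od_blank = readr::col_double()))
  blank <- mean(df$od_blank)
  vehicle <- df$od_raw[df$dose_a_nM == 0 & df$dose_b_nM == 0]
  if (!length(vehicle)) abort_pt("dose-grid CSV has no vehicle (0, 0) rows")
  surv <- normalize_viability(df$od_raw, blank, vehicle)
  df$fa <- 1 - as.numeric(surv)
  agg <- stats::aggregate(fa ~ dose_a_nM + dose_b_nM, data = df, FUN = mean)
  doses_a <- sort(unique(df$dose_a_nM))
  doses_b <- sort(unique(df$dose_b_nM))
  fa <- matrix(NA_real_, length(doses_a), length(doses_b))
  for (r in seq_len(nrow(agg))) {
    i <- match(agg$dose_a_nM[r], doses_a)
    j <- match(agg$dose_b_nM[r], doses_b)
    fa[i, j] <- min(max(agg$fa[r], 0), 1)
  }
  dose_grid(doses_a, doses_b, fa,
            drug_a = df$drug_a[df$dose_a_nM > 0][1],
            drug_b = df$drug_b[df$dose_b_nM > 0][1])
}

#' Write a dose grid as a long CSV (one replicate, synthetic OD scale)
#' @param grid a [dose_grid()]
#' @param path output path
#' @param od_vehicle,od_blank synthetic plate-reader scale anchors
#' @return `path`, invisibly
#' @export
write_dose_grid_csv <- function(grid, path, od_vehicle = 1.0, od_blank = 0.05) {
  rows <- list()
  for (i in seq_along(grid$doses_a)) {
    for (j in seq_along(grid$doses_b)) {
      surv <- 1 - grid$fa[i, j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        drug_a = grid$drug_a, dose_a_nM = grid$doses_a[i],
        drug_b = grid$drug_b, dose_b_nM = grid$doses_b[j],
        replicate = 1L,
        od_raw = od_blank + surv * (od_vehicle - od_blank),
        od_blank = od_blank)
    }
  }
  readr::write_csv(dplyr::bind_rows(rows), path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Columns `sample,gene,ct,role` with role in
#' `target|reference` and sample condition in `sample` (`control` samples
#' are the untreated calibrators).
#'
#' @param path CSV path
#' @return tibble
#' @export
read_qpcr_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(sample = readr::col_character(),
                                          gene = readr::col_character(),
                                          ct = readr::col_double(),
                                          role = readr::col_character()))
}

#' Render a publication-style single-site ITC results table
#'
#' One row per fit with the conventional columns: protein, syringe/cell
#' concentrations, K_D in nM (1 decimal, with fit SD), dH and derived
#' energies at 2 decimals, N at 2 decimals. Weak-binding fits render as the
#' text `Weak binding` with empty numeric cells. Machine-readable output
#' uses ASCII hyphen-minus throughout.
#'
#' @param fits list of `binding_fit` objects
#' @return tibble of formatted character columns: `Protein`, `P_uM`, `L_uM`,
#'   `KD_nM`, `dH_kcal_mol`, `N`, `TdS_kcal_mol`, `dG_kcal_mol`
#' @export
render_table1 <- function(fits) {
  cols <- c("Protein", "P_uM", "L_uM", "KD_nM", "dH_kcal_mol", "N",
            "TdS_kcal_mol", "dG_kcal_mol")
  if (!length(fits)) {
    out <- tibble::as_tibble(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  fmt_pm <- function(v, s, digits) {
    if (is.na(s)) sprintf("%.*f", digits, v)
    else sprintf("%.*f +/- %.*f", digits, v, digits, s)
  }
  rows <- lapply(fits, function(f) {
    if (f$weak_binding) {
      return(tibble::tibble(Protein = f$protein_id,
                            P_uM = sprintf("%g", f$syringe_conc),
                            L_uM = sprintf("%g", f$cell_conc),
                            KD_nM = "Weak binding", dH_kcal_mol = "", N = "",
                            TdS_kcal_mol = "", dG_kcal_mol = ""))
    }
    tibble::tibble(
      Protein = f$protein_id,
      P_uM = sprintf("%g", f$syringe_conc),
      L_uM = sprintf("%g", f$cell_conc),
      KD_nM = fmt_pm(f$kd, unname(f$param_errors["kd_nM"]), 1),
      dH_kcal_mol = fmt_pm(f$dh, unname(f$param_errors["dh"]), 2),
      N = fmt_pm(f$n_sites, unname(f$param_errors["n_sites"]), 2),
      TdS_kcal_mol = sprintf("%.2f", f$tds),
      dG_kcal_mol = sprintf("%.2f", f$dg)
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a `binding_fit` record from reported parameters
#'
#' Constructs the same structure [fit_single_site()] returns from already
#' known `(N, K_D, dH)` -- e.g. a published row -- deriving dG, TdS and the
#' c-value at the stated temperature. Useful for table rendering and
#' thermodynamic consistency checks.
#'
#' @param protein_id protein name
#' @param kd K_D in nM (`NA` with `weak = TRUE` for weak binders)
#' @param dh enthalpy in kcal/mol
#' @param n stoichiometry
#' @param syringe_conc,cell_conc concentrations in uM
#' @param temperature degrees C
#' @param kd_sd,dh_sd,n_sd optional 1-SD fit errors
#' @param weak weak-binding flag
#' @param gas_constant kcal/(mol K)
#' @return a `binding_fit`
#' @export
binding_fit_from_params <- function(protein_id, kd, dh, n,
                                    syringe_conc = NA_real_,
                                    cell_conc = NA_real_, temperature = 15,
                                    kd_sd = NA_real_, dh_sd = NA_real_,
                                    n_sd = NA_real_, weak = FALSE,
                                    gas_constant = R_KCAL) {
  if (weak || is.na(kd)) {
    return(structure(
      list(protein_id = protein_id, compound_id = NA_character_,
           syringe_conc = syringe_conc, cell_conc = cell_conc,
           temperature = temperature, n_sites = NA_real_, kd = NA_real_,
           dh = NA_real_, dg = NA_real_, tds = NA_real_, c_value = NA_real_,
           weak_binding = TRUE, converged = FALSE,
           param_errors = c(n_sites = NA_real_, kd_nM = NA_real_, dh = NA_real_),
           rmse = NA_real_, baseline_ucal_per_ul = NA_real_,
           saturation_warning = FALSE),
      class = "binding_fit"))
  }
  th <- derive_thermodynamics(kd, dh, temperature, gas_constant)
  structure(
    list(protein_id = protein_id, compound_id = NA_character_,
         syringe_conc = syringe_conc, cell_conc = cell_conc,
         temperature = temperature, n_sites = n, kd = kd, dh = dh,
         dg = th$dg, tds = th$tds,
         c_value = if (is.na(cell_conc)) NA_real_ else n * cell_conc * 1e-6 / (kd * 1e-9),
         weak_binding = FALSE, converged = TRUE,
         param_errors = c(n_sites = n_sd, kd_nM = kd_sd, dh = dh_sd),
         rmse = NA_real_, baseline_ucal_per_ul = NA_real_,
         saturation_warning = FALSE),
    class = "binding_fit")
}

#' Write a rendered results table as TSV
#' @param table tibble from [render_table1()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table1_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
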