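#' Construct a melt curve
#'
#' A single well's fluorescence-versus-temperature trace from a dye-based
#' thermal shift (differential scanning fluorimetry) experiment.
#'
#' @param well_id well label, e.g. `"A1"`
#' @param temperatures strictly increasing temperatures in degrees C (>= 10
#'   points, within `[0, 120]`)
#' @param fluorescence fluorescence readings (arbitrary units), same length
#' @param protein_id protein identifier
#' @param compound_id compound identifier, or `NA` for a reference
#'   (ligand-free) well
#' @param compound_conc compound concentration in uM (`NA` for reference wells)
#' @return an object of class `melt_curve`
#' @export
melt_curve <- function(well_id, temperatures, fluorescence,
                       protein_id = "protein", compound_id = NA_character_,
                       compound_conc = NA_real_) {
  temperatures <- as.numeric(temperatures)
  fluorescence <- as.numeric(fluorescence)
  if (length(temperatures) < 10)
    abort_pt("melt curve '", well_id, "': need at least 10 points")
  if (length(fluorescence) != length(temperatures))
    abort_pt("melt curve '", well_id, "': temperature/fluorescence length mismatch")
  if (any(diff(temperatures) <= 0))
    abort_pt("melt curve '", well_id, "': temperatures must be strictly increasing")
  if (min(temperatures) < 0 || max(temperatures) > 120)
    abort_pt("melt curve '", well_id, "': temperatures outside [0, 120] C")
  structure(
    list(well_id = well_id, protein_id = protein_id,
         compound_id = compound_id, compound_conc = compound_conc,
         temperatures = temperatures, fluorescence = fluorescence),
    class = "melt_curve"
  )
}

#' Two-state thermal denaturation model
#'
#' Evaluates the sigmoidal two-state unfolding model
#' \deqn{y(T) = y_F(T) + \frac{y_U(T) - y_F(T)}{1 + e^{\Delta_u G(T)/RT}}}
#' with linear native and denatured baselines
#' \eqn{y_F(T) = a_F + b_F T}, \eqn{y_U(T) = a_U + b_U T} and a van 't Hoff
#' unfolding free energy with zero heat-capacity change,
#' \eqn{\Delta_u G(T) = \Delta H_u (1 - T_K/T_{m,K})}, temperatures in kelvin.
#' At \eqn{T = T_m} the free energy vanishes and, for flat baselines, the model
#' passes exactly through \eqn{(y_F + y_U)/2}.
#'
#' @param temperature temperature(s) in degrees C (vectorized)
#' @param tm transition midpoint in degrees C
#' @param dh_unfold van 't Hoff unfolding enthalpy in kcal/mol (must be > 0)
#' @param native_baseline numeric length-2 `(intercept, slope)` of the folded
#'   baseline, AU and AU/degC
#' @param denatured_baseline `(intercept, slope)` of the unfolded baseline
#' @param gas_constant gas constant in kcal/(mol K)
#' @return fluorescence in AU, same length as `temperature`
#' @export
#' @examples
#' eval_melt_model(50, tm = 50, dh_unfold = 120,
#'                 native_baseline = c(1000, 0),
#'                 denatured_baseline = c(5000, 0)) # 3000: midpoint
eval_melt_model <- function(temperature, tm, dh_unfold,
                            native_baseline = c(0, 0),
                            denatured_baseline = c(1, 0),
                            gas_constant = R_KCAL) {
  if (!is.finite(tm) || celsius_to_kelvin(tm) <= 0)
    abort_pt("tm must be finite with positive kelvin value")
  if (!is.finite(dh_unfold) || dh_unfold <= 0)
    abort_pt("dh_unfold must be positive")
  t_k <- celsius_to_kelvin(temperature)
  tm_k <- celsius_to_kelvin(tm)
  dg <- dh_unfold * (1 - t_k / tm_k)
  frac_unfolded <- 1 / (1 + exp(dg / (gas_constant * t_k)))
  y_f <- native_baseline[1] + native_baseline[2] * temperature
  y_u <- denatured_baseline[1] + denatured_baseline[2] * temperature
  y_f + (y_u - y_f) * frac_unfolded
}

# internal: unfolded fraction at given (tm, dh), vectorized over temperature
unfolded_fraction <- function(temperature, tm, dh_unfold, gas_constant = R_KCAL) {
  t_k <- celsius_to_kelvin(temperature)
  dg <- dh_unfold * (1 - t_k / celsius_to_kelvin(tm))
  1 / (1 + exp(dg / (gas_constant * t_k)))
}

# internal: for fixed (tm, dh) the four baseline coefficients enter linearly;
# profile them with a linear least-squares solve (variable projection).
dsf_profile_baselines <- function(temperature, fluorescence, tm, dh_unfold,
                                  gas_constant = R_KCAL) {
  f <- unfolded_fraction(temperature, tm, dh_unfold, gas_constant)
  X <- cbind((1 - f), (1 - f) * temperature, f, f * temperature)
  fit <- lm.fit(X, fluorescence)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2),
       fitted = fluorescence - fit$residuals)
}

#' Flag a melt curve as unfittable (flat signal)
#'
#' A curve is considered flat when its total signal range is below
#' `noise_floor_mult` times the median absolute successive difference, i.e.
#' when there is no transition to fit above the point-to-point noise.
#'
#' @param curve a [melt_curve()]
#' @param noise_floor_mult multiplier on the median absolute successive
#'   difference (default 5)
#' @return logical
#' @export
is_flat_curve <- function(curve, noise_floor_mult = 5) {
  rng <- diff(range(curve$fluorescence))
  noise <- stats::median(abs(diff(curve$fluorescence)))
  rng < noise_floor_mult * max(noise, .Machine$double.eps)
}

#' Truncate a melt curve after the post-transition fluorescence maximum
#'
#' Dye-based melts commonly show a fluorescence decay after the unfolding
#' transition (aggregation quenching); the two-state model has no decay term,
#' so points beyond the global maximum plus a margin are dropped before
#' fitting. Monotone curves are returned unchanged (the operation is
#' idempotent).
#'
#' @param curve a [melt_curve()]
#' @param margin_C temperature margin in degrees C kept past the maximum
#' @return a [melt_curve()]
#' @export
truncate_post_transition <- function(curve, margin_C = 5) {
  i_max <- which.max(curve$fluorescence)
  t_cut <- curve$temperatures[i_max] + margin_C
  keep <- curve$temperatures <= t_cut
  if (all(keep)) return(curve)
  if (sum(keep) < 10)
    abort_pt("melt curve '", curve$well_id, "': fewer than 10 points remain after truncation")
  out <- curve
  out$temperatures <- curve$temperatures[keep]
  out$fluorescence <- curve$fluorescence[keep]
  out
}

#' Fit the two-state melt model to one well
#'
#' Nonlinear least squares of [eval_melt_model()] over six parameters: the
#' midpoint `tm`, the unfolding enthalpy `dh_unfold` and two linear baselines.
#' The baselines are profiled out by linear least squares at each candidate
#' `(tm, dh)` (variable projection), and the two nonlinear parameters are
#' optimized by Nelder-Mead with `dh_unfold` on the log scale, so positivity
#' is structural. Failure to converge, or a midpoint outside the fitted
#' temperature window, yields `converged = FALSE` -- never an error.
#'
#' @param curve a [melt_curve()]
#' @param init optional named list with any of `tm`, `dh_unfold` to override
#'   the automatic initialization
#' @param config a [default_config()] list (noise floor, gas constant,
#'   initialization enthalpy)
#' @return an object of class `melt_fit` with fields `tm`, `dh_unfold`,
#'   `native_baseline`, `denatured_baseline`, `rmse`, `converged`,
#'   `unfittable` plus the curve's identifiers
#' @export
fit_melt_curve <- function(curve, init = NULL, config = default_config()) {
  out <- structure(
    list(well_id = curve$well_id, protein_id = curve$protein_id,
         compound_id = curve$compound_id, compound_conc = curve$compound_conc,
         tm = NA_real_, dh_unfold = NA_real_,
         native_baseline = c(NA_real_, NA_real_),
         denatured_baseline = c(NA_real_, NA_real_),
         rmse = NA_real_, converged = FALSE, unfittable = FALSE),
    class = "melt_fit"
  )
  if (length(curve$fluorescence) < 10 ||
      is_flat_curve(curve, config$dsf_noise_floor_mult)) {
    out$unfittable <- TRUE
    return(out)
  }
  tt <- curve$temperatures
  yy <- curve$fluorescence
  R <- config$gas_constant

  # initialization: midpoint at the steepest rise of a lightly smoothed signal
  y_s <- stats::filter(yy, rep(1 / 5, 5), sides = 2)
  y_s[is.na(y_s)] <- yy[is.na(y_s)]
  dy <- diff(as.numeric(y_s)) / diff(tt)
  tm0 <- tt[which.max(abs(dy))]
  dh0 <- config$dsf_dh_init
  if (!is.null(init)) {
    if (!is.null(init$tm)) tm0 <- init$tm
    if (!is.null(init$dh_unfold)) dh0 <- init$dh_unfold
  }

  obj <- function(par) {
    tm <- par[1]
    dh <- exp(par[2])
    if (!is.finite(tm) || !is.finite(dh)) return(1e300)
    pr <- dsf_profile_baselines(tt, yy, tm, dh, R)
    if (!all(is.finite(pr$coef))) return(1e300)
    pr$sse
  }
  opt <- tryCatch(
    optim(c(tm0, log(dh0)), obj, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 5000)),
    error = function(e) NULL
  )
  if (is.null(opt)) return(out)
  ok <- opt$convergence == 0
  # polish with a fresh simplex; a degenerate-simplex exit (code 10) at a
  # lower SSE still counts as converged when the first pass converged
  opt2 <- tryCatch(
    optim(opt$par, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 5000)),
    error = function(e) NULL
  )
  if (!is.null(opt2) && opt2$value <= opt$value) {
    ok <- ok || opt2$convergence == 0
    opt <- opt2
  }

  tm_hat <- opt$par[1]
  dh_hat <- exp(opt$par[2])
  pr <- dsf_profile_baselines(tt, yy, tm_hat, dh_hat, R)
  out$tm <- tm_hat
  out$dh_unfold <- dh_hat
  out$native_baseline <- unname(pr$coef[1:2])
  out$denatured_baseline <- unname(pr$coef[3:4])
  out$rmse <- sqrt(pr$sse / length(yy))
  in_window <- tm_hat >= min(tt) && tm_hat <= max(tt)
  out$converged <- ok && in_window && dh_hat > 0
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> well %s  protein %s  compound %s\n",
              x$well_id, x$protein_id,
              ifelse(is.na(x$compound_id), "(reference)", x$compound_id)))
  if (x$unfittable) {
    cat("  unfittable (flat signal)\n")
  } else {
    cat(sprintf("  Tm = %.2f C  dHu = %.1f kcal/mol  rmse = %.3g AU  converged: %s\n",
                x$tm, x$dh_unfold, x$rmse, x$converged))
  }
  invisible(x)
}

#' Ligand-induced melting-temperature shift
#'
#' Each sample replicate's shift is its midpoint minus the mean midpoint of
#' the same-plate reference (ligand-free) wells; the result is the mean and
#' sample standard deviation (n - 1 denominator) over sample replicates.
#'
#' @param sample_fits list of converged `melt_fit` objects for the
#'   protein + compound wells
#' @param reference_fits list of `melt_fit` objects for the same protein's
#'   ligand-free wells (at least one converged)
#' @return a one-row tibble: `protein`, `compound`, `delta_tm_mean_C`,
#'   `delta_tm_sd_C` (`NA` when n = 1), `n`
#' @export
delta_tm <- function(sample_fits, reference_fits) {
  conv <- function(fits) Filter(function(f) isTRUE(f$converged), fits)
  samp <- conv(sample_fits)
  refs <- conv(reference_fits)
  if (length(refs) == 0)
    abort_pt("no converged reference (ligand-free) fit on this plate")
  if (length(samp) == 0)
    abort_pt("no converged sample fit")
  ref_mean <- mean(vapply(refs, `[[`, numeric(1), "tm"))
  shifts <- vapply(samp, `[[`, numeric(1), "tm") - ref_mean
  tibble::tibble(
    protein = samp[[1]]$protein_id,
    compound = samp[[1]]$compound_id,
    delta_tm_mean_C = mean(shifts),
    delta_tm_sd_C = if (length(shifts) > 1) sd(shifts) else NA_real_,
    n = length(shifts)
  )
}

#' Summarize a plate of melt fits into per-(protein, compound) shifts
#'
#' Reference wells (no compound) are averaged per protein; every
#' (protein, compound) group is reduced with [delta_tm()]. Unfittable or
#' unconverged sample wells are excluded and reported in the
#' `excluded_wells` attribute.
#'
#' @param fits list of `melt_fit` objects (identifiers attached)
#' @param plate_map optional tibble `well, protein, compound, conc_uM`
#'   overriding/declaring the identifiers; every fitted well must appear in it
#' @return tibble with one row per (protein, compound), columns as
#'   [delta_tm()]; attribute `excluded_wells` lists dropped wells
#' @export
plate_summary <- function(fits, plate_map = NULL) {
  if (!is.null(plate_map)) {
    for (i in seq_along(fits)) {
      row <- plate_map[plate_map$well == fits[[i]]$well_id, , drop = FALSE]
      if (nrow(row) == 0)
        abort_pt("well '", fits[[i]]$well_id, "' is not in the plate map")
      fits[[i]]$protein_id <- row$protein[1]
      fits[[i]]$compound_id <- row$compound[1]
      if ("conc_uM" %in% names(row)) fits[[i]]$compound_conc <- row$conc_uM[1]
    }
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  excluded <- vapply(fits[!ok], `[[`, character(1), "well_id")
  fits <- fits[ok]
  if (length(fits) == 0) abort_pt("no converged fit on the plate")
  protein <- vapply(fits, `[[`, character(1), "protein_id")
  compound <- vapply(fits, function(f) {
    if (is.na(f$compound_id) || !nzchar(f$compound_id)) NA_character_ else f$compound_id
  }, character(1))
  is_ref <- is.na(compound)
  groups <- unique(data.frame(protein = protein[!is_ref],
                              compound = compound[!is_ref],
                              stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    p <- groups$protein[i]; cm <- groups$compound[i]
    refs <- fits[is_ref & protein == p]
    if (length(refs) == 0)
      abort_pt("no reference well for protein '", p, "' on this plate")
    samp <- fits[!is_ref & protein == p & compound == cm]
    delta_tm(samp, refs)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$protein, out$compound), ]
  attr(out, "excluded_wells") <- excluded
  out
}
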