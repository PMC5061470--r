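#' Construct an ITC titration
#'
#' Reverse-geometry isothermal titration calorimetry experiment: the protein
#' (titrant) sits in the syringe and the compound (the species bearing the
#' binding sites) in the cell. The default schedule is an initial 0.3 ul
#' control injection followed by 38 identical 1 ul injections into a
#' 0.2003 ml cell at 15 degrees C.
#'
#' @param syringe_conc titrant (protein) concentration in uM
#' @param cell_conc cell-species (compound) concentration in uM
#' @param heats integrated heat of each injection in ucal, same length as
#'   `injection_volumes`
#' @param injection_volumes injection volumes in ul; the first entry is the
#'   control injection
#' @param cell_volume calorimeter cell volume in ml
#' @param temperature experiment temperature in degrees C
#' @param protein_id,compound_id identifiers
#' @return object of class `titration`
#' @export
titration <- function(syringe_conc, cell_conc, heats,
                      injection_volumes = c(0.3, rep(1, 38)),
                      cell_volume = 0.2003, temperature = 15,
                      protein_id = "protein", compound_id = "compound") {
  if (syringe_conc <= 0 || cell_conc <= 0 || cell_volume <= 0)
    abort_pt("concentrations and cell volume must be positive")
  if (any(injection_volumes <= 0))
    abort_pt("injection volumes must be positive")
  if (length(heats) != length(injection_volumes))
    abort_pt("heats and injection_volumes must have equal length")
  structure(
    list(protein_id = protein_id, compound_id = compound_id,
         syringe_conc = syringe_conc, cell_conc = cell_conc,
         cell_volume = cell_volume,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature, heats = as.numeric(heats)),
    class = "titration"
  )
}

#' Per-injection total concentrations under the displacement convention
#'
#' In an overfill-type calorimeter cell each injection displaces its own
#' volume; with cumulative injected volume \eqn{\Delta V} the standard
#' bookkeeping is
#' \deqn{[L]_{tot} = L_0 \frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0}, \qquad
#'       [P]_{tot} = P_{syr} \frac{\Delta V/V_0}{1 + \Delta V/2V_0}}
#' for the cell species and the titrant respectively. The same convention is
#' used by the forward model and the fitter.
#'
#' @param titr a [titration()]
#' @return tibble with one row per injection: `injection`, `volume_ul`,
#'   `cum_volume_ul`, `cell_total_M`, `titrant_total_M`
#' @export
injection_concentrations <- function(titr) {
  v0_ul <- titr$cell_volume * 1e3
  dv <- cumsum(titr$injection_volumes)
  if (any(dv >= v0_ul))
    abort_pt("cumulative injected volume reaches the cell volume (overfilled cell)")
  l0 <- titr$cell_conc * 1e-6
  p_syr <- titr$syringe_conc * 1e-6
  r <- dv / v0_ul
  tibble::tibble(
    injection = seq_along(dv),
    volume_ul = titr$injection_volumes,
    cum_volume_ul = dv,
    cell_total_M = l0 * (1 - r / 2) / (1 + r / 2),
    titrant_total_M = p_syr * r / (1 + r / 2)
  )
}

#' Fractional saturation of a 1:1 binding site population
#'
#' Site occupancy for titrant P binding N equivalent independent sites on the
#' cell species L with association constant \eqn{K_B = 1/K_D}: the physical
#' (smaller) root of
#' \deqn{N[L]\Theta^2 - (N[L] + [P] + K_D)\Theta + [P] = 0.}
#'
#' @param cell_total cell-species total concentration in M
#' @param titrant_total titrant total concentration in M
#' @param n stoichiometry (sites per cell-species molecule)
#' @param kd dissociation constant in M
#' @return occupancy `theta` in `[0, 1]` (vectorized)
#' @export
binding_fraction <- function(cell_total, titrant_total, n, kd) {
  if (any(cell_total < 0) || any(titrant_total < 0) || n < 0 || kd <= 0)
    abort_pt("binding_fraction needs non-negative concentrations and kd > 0")
  sites <- n * cell_total
  theta <- rep(0, length.out = max(length(cell_total), length(titrant_total)))
  pos <- sites > 0
  if (any(pos)) {
    s <- sites[pos]
    p <- rep(titrant_total, length.out = length(theta))[pos]
    b <- s + p + kd
    disc <- b^2 - 4 * s * p
    disc[disc < 0] <- 0
    # smaller quadratic root, written to avoid cancellation
    bound <- 2 * s * p / (b + sqrt(disc)) # = (b - sqrt(disc)) / 2 * ... rearranged
    theta[pos] <- pmin(pmax(bound / s, 0), 1)
  }
  theta
}

#' Forward model: per-injection heats for a single-site titration
#'
#' The cumulative heat after injection i is
#' \eqn{Q_i = N \Theta_i [L]_i \Delta H V_0}; the measured per-injection heat
#' applies the displacement correction
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}.}
#'
#' @param titr a [titration()] (its `heats` are ignored; geometry only)
#' @param n stoichiometry
#' @param kd dissociation constant in nM
#' @param dh binding enthalpy in kcal/mol
#' @return heats in ucal, one per injection (control included)
#' @export
simulate_injection_heats <- function(titr, n, kd, dh) {
  if (kd <= 0) abort_pt("kd must be positive")
  conc <- injection_concentrations(titr)
  theta <- binding_fraction(conc$cell_total_M, conc$titrant_total_M, n, kd * 1e-9)
  v0_l <- titr$cell_volume * 1e-3
  q <- n * theta * conc$cell_total_M * dh * v0_l * 1e9 # ucal
  q_prev <- c(0, q[-length(q)])
  dv_frac <- titr$injection_volumes / (titr$cell_volume * 1e3)
  q - q_prev + dv_frac * (q + q_prev) / 2
}

#' Dilution-heat baseline correction
#'
#' The titrations are designed to saturate the cell species well before the
#' final injections, so the last injections measure only the titrant's heat
#' of dilution. The baseline is the mean of the last `n_baseline` heats
#' normalized per ul, subtracted from every injection in proportion to its
#' volume; the control injection (index 1) is dropped from the returned
#' series.
#'
#' @param heats per-injection heats in ucal (control first)
#' @param injection_volumes volumes in ul, same length
#' @param n_baseline number of final injections averaged (1 reproduces the
#'   single-last-injection convention)
#' @return list with `heats` (corrected, control dropped), `volumes`,
#'   `baseline_ucal_per_ul`, and `saturation_warning` (TRUE when the last raw
#'   heat exceeds 25% of the largest heat, i.e. saturation looks incomplete)
#' @export
correct_dilution <- function(heats, injection_volumes, n_baseline = 2) {
  if (length(heats) != length(injection_volumes))
    abort_pt("heats and injection_volumes must have equal length")
  if (length(heats) < n_baseline + 3)
    abort_pt("need at least n_baseline + 3 injections")
  per_ul <- heats / injection_volumes
  baseline <- mean(tail(per_ul, n_baseline))
  corrected <- heats - baseline * injection_volumes
  # saturation check on the raw series: a last injection still carrying a
  # sizable fraction of the peak heat means binding was not saturated
  warn <- abs(tail(heats, 1)) > 0.25 * max(abs(heats))
  list(heats = corrected[-1], volumes = injection_volumes[-1],
       baseline_ucal_per_ul = baseline, saturation_warning = warn)
}

# internal: model heats per unit enthalpy, control injection dropped
itc_model_unit <- function(titr, n, kd) {
  simulate_injection_heats(titr, n, kd, dh = 1)[-1]
}

#' Fit the single-site binding model to a titration
#'
#' Least squares of the forward model over (N, K_D, dH) plus a
#' volume-proportional dilution baseline, against the post-control heats.
#' dH and the baseline enter linearly and are profiled out at each candidate
#' (N, K_D) (variable projection); the two nonlinear parameters are
#' optimized on the log scale by Nelder-Mead from a small multistart grid of
#' K_D initializations. Estimating the dilution baseline jointly from the
#' whole series is statistically efficient and coincides with the
#' last-injection convention of [correct_dilution()] when the titration is
#' saturated; noiseless parameter recovery is exact either way. Parameter
#' standard errors come from the Jacobian at the optimum
#' (`sigma^2 (J'J)^{-1}`, four parameters). Optimizer failure, K_D above the
#' weak-binding threshold, c below the c threshold, or an essentially flat
#' heat series set `weak_binding = TRUE` (never an error).
#'
#' @param titr a [titration()] with measured `heats`
#' @param config a [default_config()] list (`itc_n_baseline`, `weak_kd_nM`,
#'   `weak_c_value`, `itc_min_signal_ucal`, gas constant)
#' @return object of class `binding_fit`: `n_sites`, `kd` (nM), `dh`, `dg`,
#'   `tds` (kcal/mol), `c_value`, `weak_binding`, `param_errors` (SDs for
#'   n_sites, kd_nM, dh), `rmse`, `converged`, `baseline_ucal_per_ul`,
#'   `temperature`, ids and concentrations
#' @export
fit_single_site <- function(titr, config = default_config()) {
  nb <- config$itc_n_baseline
  if (length(titr$heats) - 1 < 10)
    abort_pt("need at least 10 retained injections")
  corr <- correct_dilution(titr$heats, titr$injection_volumes, nb)
  d <- corr$heats

  out <- structure(
    list(protein_id = titr$protein_id, compound_id = titr$compound_id,
         syringe_conc = titr$syringe_conc, cell_conc = titr$cell_conc,
         temperature = titr$temperature,
         n_sites = NA_real_, kd = NA_real_, dh = NA_real_,
         dg = NA_real_, tds = NA_real_, c_value = NA_real_,
         weak_binding = FALSE, converged = FALSE,
         param_errors = c(n_sites = NA_real_, kd_nM = NA_real_, dh = NA_real_),
         rmse = NA_real_,
         baseline_ucal_per_ul = corr$baseline_ucal_per_ul,
         saturation_warning = corr$saturation_warning),
    class = "binding_fit"
  )

  if (max(abs(d)) < config$itc_min_signal_ucal) {
    out$weak_binding <- TRUE
    out$note <- "no measurable binding heat"
    return(out)
  }

  y <- titr$heats[-1]
  v <- titr$injection_volumes[-1]
  profile_lin <- function(g) {
    fit <- lm.fit(cbind(g, v), y)
    list(dh = unname(fit$coefficients[1]),
         baseline = unname(fit$coefficients[2]),
         sse = sum(fit$residuals^2))
  }
  obj <- function(par) {
    n <- exp(par[1]); kd <- exp(par[2])
    g <- itc_model_unit(titr, n, kd)
    if (!all(is.finite(g)) || sum(g * g) == 0) return(1e300)
    pr <- profile_lin(g)
    if (!is.finite(pr$sse)) return(1e300)
    pr$sse
  }

  kd_starts <- titr$cell_conc * 1e3 / c(1000, 100, 10, 1) # nM, c = 1000..1
  best <- NULL
  for (kd0 in kd_starts) {
    opt <- tryCatch(
      optim(c(log(1), log(kd0)), obj, method = "Nelder-Mead",
            control = list(reltol = 1e-12, maxit = 5000)),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) {
    out$weak_binding <- TRUE
    out$note <- "optimizer failure"
    return(out)
  }
  ok <- best$convergence == 0
  # restart polish; accept a degenerate-simplex exit at a lower SSE
  best2 <- tryCatch(
    optim(best$par, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 5000)),
    error = function(e) NULL
  )
  if (!is.null(best2) && best2$value <= best$value) {
    ok <- ok || best2$convergence == 0
    best <- best2
  }

  n_hat <- exp(best$par[1]); kd_hat <- exp(best$par[2])
  pr <- profile_lin(itc_model_unit(titr, n_hat, kd_hat))
  dh_hat <- pr$dh
  m <- length(y)
  sse <- pr$sse

  # 1-SD errors from the Jacobian wrt (n, kd_nM, dh, baseline)
  model_fun <- function(th) th[3] * itc_model_unit(titr, th[1], th[2]) + th[4] * v
  th <- c(n_hat, kd_hat, dh_hat, pr$baseline)
  J <- matrix(0, m, 4)
  for (j in 1:4) {
    h <- max(abs(th[j]), 1e-8) * 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm_ <- th; tm_[j] <- tm_[j] - h
    J[, j] <- (model_fun(tp) - model_fun(tm_)) / (2 * h)
  }
  sigma2 <- sse / max(m - 4, 1)
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(cov)) {
    se <- sqrt(pmax(diag(cov), 0))
    out$param_errors <- c(n_sites = se[1], kd_nM = se[2], dh = se[3])
  }
  out$fitted_baseline_ucal_per_ul <- pr$baseline

  thermo <- derive_thermodynamics(kd_hat, dh_hat, titr$temperature,
                                  gas_constant = config$gas_constant)
  out$n_sites <- n_hat
  out$kd <- kd_hat
  out$dh <- dh_hat
  out$dg <- thermo$dg
  out$tds <- thermo$tds
  out$c_value <- n_hat * (titr$cell_conc * 1e-6) / (kd_hat * 1e-9)
  out$rmse <- sqrt(sse / m)
  out$converged <- ok
  out$weak_binding <- !out$converged ||
    kd_hat > config$weak_kd_nM || out$c_value < config$weak_c_value
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s + %s\n", x$protein_id, x$compound_id))
  if (x$weak_binding && is.na(x$kd)) {
    cat("  Weak binding (no fit)\n")
    return(invisible(x))
  }
  cat(sprintf("  N = %.3f  KD = %.1f nM  dH = %.2f  dG = %.2f  TdS = %.2f kcal/mol  c = %.0f%s\n",
              x$n_sites, x$kd, x$dh, x$dg, x$tds, x$c_value,
              if (x$weak_binding) "  [weak binding]" else ""))
  invisible(x)
}

#' Free energy and entropy from dissociation constant and enthalpy
#'
#' \eqn{\Delta G = RT \ln K_D} (K_D in molar, i.e. \eqn{-RT \ln K_B}) and
#' \eqn{T\Delta S = \Delta H - \Delta G}.
#'
#' @param kd dissociation constant in nM (> 0)
#' @param dh binding enthalpy in kcal/mol (`NA` allowed if only dg is needed)
#' @param temperature temperature in degrees C
#' @param gas_constant gas constant in kcal/(mol K)
#' @return list with `dg` and `tds` in kcal/mol
#' @export
#' @examples
#' derive_thermodynamics(41.8, -11.09, 15) # dg ~ -9.73, tds ~ -1.36
derive_thermodynamics <- function(kd, dh = NA_real_, temperature = 15,
                                  gas_constant = R_KCAL) {
  if (any(!is.finite(kd)) || any(kd <= 0)) abort_pt("kd must be positive")
  t_k <- celsius_to_kelvin(temperature)
  dg <- gas_constant * t_k * log(kd * 1e-9)
  list(dg = dg, tds = dh - dg)
}

#' Dilution-corrected binding isotherm
#'
#' Normalized heat per mole of injectant versus the molar ratio of titrant to
#' cell species, after dilution correction; the control injection is
#' excluded. This is the sigmoid conventionally plotted for an ITC
#' experiment, with its inflection near molar ratio N.
#'
#' @param titr a [titration()]
#' @param n_baseline final injections averaged for the dilution baseline
#' @return tibble `molar_ratio`, `ndh_kcal_per_mol`
#' @export
to_isotherm <- function(titr, n_baseline = 2) {
  corr <- correct_dilution(titr$heats, titr$injection_volumes, n_baseline)
  conc <- injection_concentrations(titr)[-1, ]
  moles_injected <- titr$syringe_conc * 1e-6 * corr$volumes * 1e-6 # mol
  tibble::tibble(
    molar_ratio = conc$titrant_total_M / conc$cell_total_M,
    ndh_kcal_per_mol = corr$heats * 1e-9 / moles_injected
  )
}

#' Bin a dissociation constant into an affinity class
#'
#' @param kd dissociation constant in nM (vectorized)
#' @param weak logical, weak-binding flag(s); weak entries label as "weak"
#' @param edges_nM increasing bin edges in nM (boundaries inclusive on the
#'   tighter side)
#' @return character vector of class labels
#' @export
#' @examples
#' classify_affinity(c(41.8, 100, 4762)) # "<=100 nM", "<=100 nM", "1-10 uM"
classify_affinity <- function(kd, weak = FALSE,
                              edges_nM = c(100, 1000, 10000)) {
  labels <- c("<=100 nM", "100 nM-1 uM", "1-10 uM", ">10 uM")
  weak <- rep(weak, length.out = length(kd))
  out <- character(length(kd))
  for (i in seq_along(kd)) {
    if (weak[i]) { out[i] <- "weak"; next }
    if (kd[i] <= 0) abort_pt("kd must be positive")
    # boundaries belong to the tighter bin: (edge_{j-1}, edge_j]
    out[i] <- labels[findInterval(kd[i], edges_nM, left.open = TRUE) + 1]
  }
  out
}
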