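#' Vehicle-normalized cell viability
#'
#' Blank-subtracted readings scaled to the vehicle (DMSO) control mean:
#' `(raw - blank) / (mean(vehicle) - blank)`, clipped to a configurable range
#' (default `[0, 1.5]`; the number of clipped wells is recorded in the
#' `clipped` attribute). Fraction affected is `fa = 1 - surviving`.
#'
#' @param raw raw absorbance/luminescence readings (vectorized)
#' @param blank blank (no-cell) control reading
#' @param vehicle vehicle-control replicate readings
#' @param clip length-2 clipping range for the surviving fraction
#' @return surviving fractions with attribute `clipped`
#' @export
normalize_viability <- function(raw, blank, vehicle, clip = c(0, 1.5)) {
  veh <- mean(vehicle)
  if (veh <= blank)
    abort_pt("vehicle mean must exceed the blank")
  surv <- (raw - blank) / (veh - blank)
  n_clip <- sum(surv < clip[1] | surv > clip[2])
  surv <- pmin(pmax(surv, clip[1]), clip[2])
  attr(surv, "clipped") <- n_clip
  surv
}

#' Four-parameter logistic dose-response fit
#'
#' Fits `surviving = bottom + (top - bottom) / (1 + (d / ec50)^hill)` by
#' least squares; `top` and `bottom` are profiled linearly, and
#' `(log ec50, log hill)` are optimized by Nelder-Mead. Flat data (response
#' range below `min_span`) returns `converged = FALSE`.
#'
#' @param doses doses in nM (zero allowed; at least 5 distinct values)
#' @param surviving surviving fractions, same length
#' @param min_span minimum response range treated as a real transition
#' @return list: `ec50` (nM), `hill`, `top`, `bottom`, `rmse`, `converged`,
#'   `ec50_in_range`
#' @export
fit_dose_response <- function(doses, surviving, min_span = 0.1) {
  if (length(unique(doses)) < 5)
    abort_pt("need at least 5 distinct doses")
  out <- list(ec50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_, rmse = NA_real_, converged = FALSE,
              ec50_in_range = NA)
  if (diff(range(surviving)) < min_span) return(out)
  profile_lin <- function(ec50, hill) {
    f <- 1 / (1 + (doses / ec50)^hill) # 1 at d = 0, decreasing
    X <- cbind(1, f)
    fit <- lm.fit(X, surviving)
    list(coef = fit$coefficients, sse = sum(fit$residuals^2))
  }
  obj <- function(par) {
    pr <- profile_lin(exp(par[1]), exp(par[2]))
    if (!all(is.finite(pr$coef))) return(1e300)
    pr$sse
  }
  pos <- doses[doses > 0]
  start <- c(log(stats::median(pos)), log(1))
  opt <- tryCatch(
    optim(start, obj, method = "Nelder-Mead",
          control = list(reltol = 1e-15, maxit = 5000)),
    error = function(e) NULL
  )
  if (is.null(opt)) return(out)
  opt <- tryCatch(optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-15, maxit = 5000)),
                  error = function(e) opt)
  ec50 <- exp(opt$par[1]); hill <- exp(opt$par[2])
  pr <- profile_lin(ec50, hill)
  out$ec50 <- ec50
  out$hill <- hill
  out$bottom <- unname(pr$coef[1])
  out$top <- unname(pr$coef[1] + pr$coef[2])
  out$rmse <- sqrt(pr$sse / length(surviving))
  out$converged <- opt$convergence == 0
  out$ec50_in_range <- ec50 >= min(pos) && ec50 <= max(pos)
  out
}

#' Median-effect (Chou) fit of a single-agent dose-response
#'
#' Linear regression of the median-effect transform
#' `log(fa / (1 - fa)) = m log(D) - m log(Dm)`; the slope is the sigmoidicity
#' m and the intercept gives the median-effect dose Dm (fa = 0.5 at Dm).
#' Boundary fractions are clipped into `fa_clip` before the logit; doses with
#' fa outside (0, 1) after clipping are dropped. At least 3 usable points
#' are required.
#'
#' @param doses doses in nM (> 0)
#' @param fa fractions affected in `[0, 1]`
#' @param fa_clip clipping range applied before the logit
#' @return list of class `median_effect_fit`: `dm` (nM), `m`, `r2`,
#'   `n_points`
#' @export
median_effect_fit <- function(doses, fa, fa_clip = c(0.01, 0.99)) {
  keep <- doses > 0 & is.finite(fa)
  doses <- doses[keep]; fa <- fa[keep]
  fa <- pmin(pmax(fa, fa_clip[1]), fa_clip[2])
  usable <- fa > 0 & fa < 1
  if (sum(usable) < 3)
    abort_pt("median-effect fit needs at least 3 doses with 0 < fa < 1")
  x <- log(doses[usable])
  y <- log(fa[usable] / (1 - fa[usable]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0)
    abort_pt("median-effect slope must be positive (is the response increasing with dose?)")
  dm <- exp(-unname(stats::coef(fit)[1]) / m)
  r2 <- suppressWarnings(summary(fit)$r.squared) # noiseless data fits exactly
  structure(list(dm = dm, m = m, r2 = r2,
                 n_points = sum(usable)),
            class = "median_effect_fit")
}

#' Dose producing a given effect under a median-effect fit
#'
#' @param fit a [median_effect_fit()]
#' @param fa fraction affected in (0, 1)
#' @return dose `Dx` in nM such that the model yields `fa`
#' @export
effect_dose <- function(fit, fa) {
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Construct a checkerboard dose grid
#'
#' @param doses_a,doses_b single-agent dose levels in nM, increasing,
#'   beginning with 0 (the 0 row/column holds the other drug's single-agent
#'   data)
#' @param fa matrix of fractions affected, rows indexed by drug-A dose,
#'   columns by drug-B dose
#' @param drug_a,drug_b drug names
#' @return object of class `dose_grid`
#' @export
dose_grid <- function(doses_a, doses_b, fa, drug_a = "drugA", drug_b = "drugB") {
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0))
    abort_pt("doses must be strictly increasing")
  if (any(doses_a < 0) || any(doses_b < 0)) abort_pt("doses must be >= 0")
  fa <- as.matrix(fa)
  if (nrow(fa) != length(doses_a) || ncol(fa) != length(doses_b))
    abort_pt("fa matrix dimensions must match the dose vectors")
  if (any(fa < 0 | fa > 1, na.rm = TRUE)) abort_pt("fa must lie in [0, 1]")
  structure(list(doses_a = doses_a, doses_b = doses_b, fa = fa,
                 drug_a = drug_a, drug_b = drug_b),
            class = "dose_grid")
}

#' Chou-Talalay combination index over a checkerboard
#'
#' For every grid point with fraction affected strictly inside (0, 1) the
#' combination index is
#' \deqn{CI = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}}}
#' where `Dx_i` is the dose of drug i alone producing the point's fa under
#' its median-effect fit (mutually exclusive form, the conventional default
#' for a non-constant-ratio checkerboard). `cross_term = TRUE` adds the
#' mutually nonexclusive term `d1 d2 / (Dx1 Dx2)`. CI < 1 indicates synergy,
#' 1 additivity, > 1 antagonism. Points with boundary fa are skipped and
#' listed in the `skipped` attribute.
#'
#' @param grid a [dose_grid()]
#' @param fit_a,fit_b [median_effect_fit()]s of the two single agents
#' @param cross_term include the mutually nonexclusive cross term
#' @return tibble `d1`, `d2`, `fa`, `ci`; attribute `skipped` counts skipped
#'   points
#' @export
combination_index <- function(grid, fit_a, fit_b, cross_term = FALSE) {
  rows <- list()
  skipped <- 0L
  for (i in seq_along(grid$doses_a)) {
    for (j in seq_along(grid$doses_b)) {
      d1 <- grid$doses_a[i]; d2 <- grid$doses_b[j]
      if (d1 == 0 && d2 == 0) next
      fa <- grid$fa[i, j]
      if (!is.finite(fa) || fa <= 0 || fa >= 1) { skipped <- skipped + 1L; next }
      dx1 <- effect_dose(fit_a, fa)
      dx2 <- effect_dose(fit_b, fa)
      ci <- d1 / dx1 + d2 / dx2
      if (cross_term) ci <- ci + (d1 * d2) / (dx1 * dx2)
      rows[[length(rows) + 1L]] <- tibble::tibble(d1 = d1, d2 = d2,
                                                  fa = fa, ci = ci)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control)]`
#' with a housekeeping reference gene as endogenous control.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   threshold-cycle values (vectorized)
#' @return fold change relative to the control condition
#' @export
#' @examples
#' ddct_fold_change(20, 15, 18, 15) # 0.25
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
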