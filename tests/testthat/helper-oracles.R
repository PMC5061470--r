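# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (direct formula evaluation, bisection, grid
# search) so that fits can be cross-checked against them.

# Site occupancy by bisection on the mass-action balance:
# bound B satisfies (sites - B)(P - B)/Kd - B = 0 on [0, min(sites, P)].
oracle_theta_bisect <- function(cell_total, titrant_total, n, kd) {
  sites <- n * cell_total
  if (sites <= 0 || titrant_total <= 0) return(0)
  f <- function(b) (sites - b) * (titrant_total - b) / kd - b
  lo <- 0; hi <- min(sites, titrant_total)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / sites
}

# SSE of the two-state melt model at (tm, dh) with baselines profiled by an
# independent linear solve (qr.solve, not the package helper).
oracle_dsf_sse <- function(temperature, fluorescence, tm, dh,
                           gas_constant = 1.9872e-3) {
  t_k <- temperature + 273.15
  dg <- dh * (1 - t_k / (tm + 273.15))
  f <- 1 / (1 + exp(dg / (gas_constant * t_k)))
  X <- cbind(1 - f, (1 - f) * temperature, f, f * temperature)
  beta <- qr.solve(X, fluorescence)
  sum((fluorescence - X %*% beta)^2)
}

# Brute-force grid minimum of the profiled SSE over (tm, dh).
oracle_dsf_grid_min <- function(temperature, fluorescence,
                                tm_grid, dh_grid) {
  best <- c(NA, NA); best_sse <- Inf
  for (tm in tm_grid) {
    for (dh in dh_grid) {
      s <- oracle_dsf_sse(temperature, fluorescence, tm, dh)
      if (s < best_sse) { best_sse <- s; best <- c(tm, dh) }
    }
  }
  list(tm = best[1], dh = best[2], sse = best_sse)
}

# Noiseless synthetic melt curve straight from the closed-form model
# (independent arithmetic, no package call).
oracle_melt_curve_values <- function(temperature, tm, dh, yf, yu,
                                     gas_constant = 1.9872e-3) {
  t_k <- temperature + 273.15
  dg <- dh * (1 - t_k / (tm + 273.15))
  y_f <- yf[1] + yf[2] * temperature
  y_u <- yu[1] + yu[2] * temperature
  y_f + (y_u - y_f) / (1 + exp(dg / (gas_constant * t_k)))
}
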