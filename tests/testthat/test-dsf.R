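test_that("melt model hits the flat-baseline midpoint and step limits", {
  # midpoint by symmetry of the logistic
  expect_equal(eval_melt_model(50, 50, 120, c(1000, 0), c(5000, 0)), 3000,
               tolerance = 1e-12)
  # arbitrary positive enthalpy does not move the midpoint
  for (dh in c(10, 120, 500))
    expect_lt(abs(eval_melt_model(50, 50, dh, c(1000, 0), c(5000, 0)) - 3000),
              1e-9)
  # step-function limit: just below the midpoint the signal sits on y_F
  expect_equal(eval_melt_model(49, 50, 1e6, c(1000, 0), c(5000, 0)), 1000,
               tolerance = 1e-6)
  # hand evaluation of the printed equation at T = 55, Tm = 50, dH = 120
  expect_equal(eval_melt_model(55, 50, 120, c(1000, 0), c(5000, 0)),
               4780.715624, tolerance = 1e-8)
  expect_error(eval_melt_model(55, 50, -5), "positive")
})

test_that("melt model is continuous and monotone between flat baselines", {
  tg <- seq(25, 96, 0.1)
  y <- eval_melt_model(tg, 60, 100, c(1000, 0), c(5000, 0))
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 1000 & y <= 5000))
})

test_that("noiseless melt curves are recovered to sub-millikelvin accuracy", {
  tg <- seq(25, 96, 0.5)
  cases <- list(
    list(tm = 50, dh = 120, yf = c(1000, 0), yu = c(5000, 0)),
    list(tm = 62.3, dh = 85, yf = c(800, 3), yu = c(5200, -6)),
    list(tm = 45.7, dh = 150, yf = c(1200, -2), yu = c(4800, -4))
  )
  for (cs in cases) {
    y <- oracle_melt_curve_values(tg, cs$tm, cs$dh, cs$yf, cs$yu)
    fit <- fit_melt_curve(melt_curve("w", tg, y))
    expect_true(fit$converged)
    expect_lt(abs(fit$tm - cs$tm), 1e-3)
    expect_lt(abs(fit$dh_unfold - cs$dh) / cs$dh, 1e-3)
  }
})

test_that("fitted midpoint error stays below 0.2 C under 1% range noise", {
  tg <- seq(25, 96, 0.5)
  y0 <- oracle_melt_curve_values(tg, 50, 120, c(1000, 0), c(5000, 0))
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    y <- y0 + rnorm(length(y0), sd = 0.01 * 4000)
    fit <- fit_melt_curve(melt_curve("w", tg, y))
    abs(fit$tm - 50)
  }, numeric(1))
  expect_lt(mean(errs), 0.2)
})

test_that("fitted optimum matches the brute-force SSE grid minimum", {
  tg <- seq(25, 96, 0.5)
  set.seed(11)
  for (rep in 1:5) {
    tm_true <- runif(1, 45, 65)
    dh_true <- runif(1, 80, 160)
    y <- oracle_melt_curve_values(tg, tm_true, dh_true, c(1000, -2), c(5000, -5)) +
      rnorm(length(tg), sd = 20)
    fit <- fit_melt_curve(melt_curve("w", tg, y))
    grid <- oracle_dsf_grid_min(tg, y,
                                tm_grid = seq(tm_true - 3, tm_true + 3, 0.1),
                                dh_grid = seq(dh_true - 50, dh_true + 50, 5))
    # same cell at grid resolution, and at least as good an SSE
    expect_lt(abs(fit$tm - grid$tm), 0.1 + 1e-9)
    expect_lt(abs(fit$dh_unfold - grid$dh), 5 + 1e-9)
    expect_lte(oracle_dsf_sse(tg, y, fit$tm, fit$dh_unfold),
               grid$sse * (1 + 1e-9))
  }
})

test_that("raising the generating midpoint strictly raises the fitted one", {
  tg <- seq(25, 96, 0.5)
  tms <- c(45, 50, 55, 60, 65)
  fitted <- vapply(tms, function(tm) {
    y <- oracle_melt_curve_values(tg, tm, 120, c(1000, 0), c(5000, 0))
    fit_melt_curve(melt_curve("w", tg, y))$tm
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("flat or short signals are flagged unfittable, not fitted", {
  tg <- seq(25, 96, 0.5)
  flat <- melt_curve("w", tg, rep(1000, length(tg)) + sin(seq_along(tg)) * 0.1)
  fit <- fit_melt_curve(flat)
  expect_true(fit$unfittable)
  expect_false(fit$converged)
  expect_error(melt_curve("w", tg[1:5], 1:5), "at least 10")
})

test_that("post-transition truncation clips the decay and is idempotent", {
  tg <- seq(25, 96, 0.5)
  rising <- melt_curve("w", tg, seq(1000, 5000, length.out = length(tg)))
  expect_identical(truncate_post_transition(rising), rising)
  # rises to a maximum at 70 C then decays (aggregation artifact)
  y <- ifelse(tg <= 70, 1000 + (tg - 25) * 80, 1000 + 45 * 80 - (tg - 70) * 60)
  cv <- melt_curve("w", tg, y)
  tr <- truncate_post_transition(cv, margin_C = 5)
  expect_lte(max(tr$temperatures), 75)
  expect_identical(truncate_post_transition(tr, margin_C = 5), tr)
  # maximum at the final point: untouched
  expect_identical(truncate_post_transition(rising, margin_C = 0), rising)
})

make_fit <- function(tm, protein = "P1", compound = "C1", converged = TRUE) {
  structure(list(well_id = "w", protein_id = protein, compound_id = compound,
                 compound_conc = 10, tm = tm, dh_unfold = 120,
                 native_baseline = c(0, 0), denatured_baseline = c(1, 0),
                 rmse = 0, converged = converged, unfittable = FALSE),
            class = "melt_fit")
}

test_that("delta-Tm replicate arithmetic matches the reference convention", {
  refs <- lapply(c(50, 50, 50), make_fit, compound = NA_character_)
  same <- lapply(c(50, 50, 50), make_fit)
  r0 <- delta_tm(same, refs)
  expect_equal(r0$delta_tm_mean_C, 0)
  expect_equal(r0$delta_tm_sd_C, 0)

  refs2 <- lapply(c(49.8, 50.0, 50.2), make_fit, compound = NA_character_)
  samp2 <- lapply(c(53, 53, 53), make_fit)
  r2 <- delta_tm(samp2, refs2)
  expect_equal(r2$delta_tm_mean_C, 3.0, tolerance = 1e-12)
  expect_equal(r2$delta_tm_sd_C, 0, tolerance = 1e-12)

  r3 <- delta_tm(lapply(c(52, 53, 54), make_fit), refs)
  expect_equal(r3$delta_tm_mean_C, 3.0)
  expect_equal(r3$delta_tm_sd_C, 1.0) # sample SD, n - 1 denominator
  expect_equal(r3$n, 3L)

  r1 <- delta_tm(list(make_fit(53)), refs)
  expect_true(is.na(r1$delta_tm_sd_C)) # single replicate: no SD

  expect_error(delta_tm(same, lapply(50, make_fit, converged = FALSE)),
               "reference")
})

test_that("plate summary groups wells, drops unfittable ones, checks the map", {
  fits <- c(
    lapply(c(50, 50, 50), make_fit, protein = "P1", compound = NA_character_),
    lapply(c(53, 53, 53), make_fit, protein = "P1", compound = "C1"),
    lapply(c(49, 49, 49), make_fit, protein = "P2", compound = NA_character_),
    lapply(c(51, 51, 51), make_fit, protein = "P2", compound = "C1")
  )
  summ <- plate_summary(fits)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$delta_tm_mean_C, c(3, 2))

  # one sample replicate fails to fit -> n drops to 2
  fits2 <- c(lapply(c(50, 50, 50), make_fit, compound = NA_character_),
             lapply(c(53, 53), make_fit),
             list(make_fit(53, converged = FALSE)))
  s2 <- plate_summary(fits2)
  expect_equal(s2$n, 2L)
  expect_equal(attr(s2, "excluded_wells"), "w")

  pm <- tibble::tibble(well = "other", protein = "P1",
                       compound = NA_character_, conc_uM = NA_real_)
  expect_error(plate_summary(fits, pm), "not in the plate map")
})

test_that("a plate emulating the published panel design yields 24 rows", {
  spec <- dtm_panel_plate_spec()
  expect_equal(nrow(spec), 12 * 3 + 12 * 2 * 3) # refs + 2 compounds, triplicate
  plate <- gen_melt_plate(spec, noise_sd = 0, seed = 1)
  fits <- lapply(plate$curves, fit_melt_curve)
  summ <- plate_summary(fits)
  expect_equal(nrow(summ), 24)
  # noiseless round trip recovers the programmed shifts
  truth <- bsp_dtm_panel()
  joined <- merge(summ, truth, by = c("protein", "compound"))
  expect_equal(nrow(joined), 24)
  expect_lt(max(abs(joined$delta_tm_mean_C.x - joined$delta_tm_mean_C.y)), 1e-3)
})
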