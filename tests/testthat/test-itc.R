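make_titr <- function(syringe = 258, cell = 20, heats = rep(0, 39)) {
  titration(syringe, cell, heats)
}

test_that("displacement bookkeeping follows the stated convention", {
  titr <- make_titr()
  conc <- injection_concentrations(titr)
  expect_equal(nrow(conc), 39)
  expect_equal(conc$cum_volume_ul[39], 38.3) # 0.3 + 38 x 1 ul
  # hand evaluation of the displacement formulas at a few injections
  v0 <- 200.3
  for (i in c(1, 5, 39)) {
    dv <- conc$cum_volume_ul[i]
    r <- dv / v0
    expect_equal(conc$cell_total_M[i], 20e-6 * (1 - r / 2) / (1 + r / 2),
                 tolerance = 1e-12)
    expect_equal(conc$titrant_total_M[i], 258e-6 * r / (1 + r / 2),
                 tolerance = 1e-12)
  }
  # zero titrant in the syringe stays zero in the cell
  conc0 <- injection_concentrations(make_titr(syringe = 1e-9))
  expect_true(all(conc0$titrant_total_M < 1e-14))
  # overfilled cell is rejected
  expect_error(
    injection_concentrations(titration(258, 20, rep(0, 300),
                                       injection_volumes = rep(1, 300))),
    "overfilled")
})

test_that("binding fraction solves the 1:1 quadratic and matches bisection", {
  expect_equal(binding_fraction(20e-6, 0, 1, 41.8e-9), 0)
  # stoichiometric (infinite-affinity) limit
  expect_equal(binding_fraction(20e-6, 10e-6, 1, 1e-18), 0.5, tolerance = 1e-9)
  # spec'd spot case against the bisection oracle
  th <- binding_fraction(20e-6, 10e-6, 1, 41.8e-9)
  expect_equal(th, oracle_theta_bisect(20e-6, 10e-6, 1, 41.8e-9),
               tolerance = 1e-10)
  # property sweep: bounds and oracle agreement over random admissible inputs
  set.seed(42)
  n_cases <- 2000
  cells <- 10^runif(n_cases, -7, -3)
  titrants <- 10^runif(n_cases, -8, -3)
  ns <- runif(n_cases, 0.5, 2)
  kds <- 10^runif(n_cases, -10, -4)
  for (i in seq_len(n_cases)) {
    th <- binding_fraction(cells[i], titrants[i], ns[i], kds[i])
    expect_gte(th, 0); expect_lte(th, 1)
    expect_equal(th, oracle_theta_bisect(cells[i], titrants[i], ns[i], kds[i]),
                 tolerance = 1e-10)
  }
})

test_that("forward heats obey the zero, tight-binding and saturation limits", {
  titr <- make_titr()
  expect_equal(simulate_injection_heats(titr, 1, 41.8, 0), rep(0, 39))
  # tight binding: normalized heats step from dH to ~0 at molar ratio N
  tight <- make_titr()
  tight$heats <- simulate_injection_heats(tight, 1, 1e-6, -10) # kd = 1e-15 M
  iso <- to_isotherm(tight, n_baseline = 1)
  pre <- iso$ndh_kcal_per_mol[iso$molar_ratio < 0.9]
  post <- iso$ndh_kcal_per_mol[iso$molar_ratio > 1.1]
  expect_lt(max(abs(pre - (-10))), 0.05)
  expect_lt(max(abs(post)), 0.05)
  # the standard reverse-geometry run saturates the cell species > 99%
  conc <- injection_concentrations(titr)
  theta_final <- binding_fraction(conc$cell_total_M[39], conc$titrant_total_M[39],
                                  0.94, 41.8e-9)
  expect_gt(theta_final, 0.99)
})

test_that("heat conservation holds in the tight-binding limit", {
  titr <- make_titr()
  heats <- simulate_injection_heats(titr, 1, 1e-6, -10)
  total <- sum(heats)
  # N * L0 * V0 * dH in ucal, displacement terms allowed up to 5%
  expected <- 1 * 20e-6 * 0.2003e-3 * (-10) * 1e9
  expect_lt(abs(total - expected) / abs(expected), 0.05)
})

test_that("dilution correction removes per-volume offsets and recovers them", {
  vols <- c(0.3, rep(1, 38))
  # pure offset: corrected heats vanish
  corr <- correct_dilution(0.7 * vols, vols, n_baseline = 2)
  expect_equal(corr$heats, rep(0, 38), tolerance = 1e-12)
  expect_equal(corr$baseline_ucal_per_ul, 0.7)
  # synthetic binding signal + 0.5 ucal/ul offset, noiseless
  sim <- gen_titration(dilution_offset = 0.5, noise_sd = 0)
  corr2 <- correct_dilution(sim$titration$heats, vols, n_baseline = 2)
  expect_lt(abs(corr2$baseline_ucal_per_ul - 0.5) / 0.5, 0.01)
  # n_baseline = 1 reproduces the single-last-injection convention
  corr3 <- correct_dilution(sim$titration$heats, vols, n_baseline = 1)
  expect_equal(corr3$baseline_ucal_per_ul,
               sim$titration$heats[39] / vols[39])
  # an unsaturated titration attaches a warning flag
  sim_weak <- gen_titration(kd = 2e5, noise_sd = 0, dilution_offset = 0)
  corr4 <- correct_dilution(sim_weak$titration$heats, vols, 2)
  expect_true(corr4$saturation_warning)
  expect_error(correct_dilution(1:4, rep(1, 4), n_baseline = 2), "at least")
})

test_that("single-site fits recover generating parameters", {
  sim <- gen_titration(n = 0.94, kd = 41.8, dh = -11.09, noise_sd = 0,
                       dilution_offset = 0.5)
  fit <- fit_single_site(sim$titration)
  expect_false(fit$weak_binding)
  expect_lt(abs(fit$n_sites - 0.94) / 0.94, 1e-4)
  expect_lt(abs(fit$kd - 41.8) / 41.8, 1e-4)
  expect_lt(abs(fit$dh - (-11.09)) / 11.09, 1e-4)
  # round trip across random parameter draws, c in [5, 1000]
  set.seed(7)
  for (rep in 1:10) {
    cell <- runif(1, 13, 25)
    c_val <- 10^runif(1, log10(5), 3)
    n_true <- runif(1, 0.9, 1.1)
    kd_true <- n_true * cell * 1e3 / c_val # nM
    dh_true <- runif(1, -15, -3)
    sim <- gen_titration(n = n_true, kd = kd_true, dh = dh_true,
                         cell_conc = cell, syringe_conc = 15 * cell,
                         noise_sd = 0, dilution_offset = 0.3)
    fit <- fit_single_site(sim$titration)
    expect_lt(abs(fit$kd - kd_true) / kd_true, 1e-4)
    expect_lt(abs(fit$n_sites - n_true) / n_true, 1e-4)
    expect_lt(abs(fit$dh - dh_true) / abs(dh_true), 1e-4)
  }
})

test_that("flat heats and failed optimizations flag weak binding", {
  titr <- make_titr(heats = rep(0, 39))
  fit <- fit_single_site(titr)
  expect_true(fit$weak_binding)
  # micromolar binder at low c is classified weak by the c-value rule
  sim <- gen_titration(kd = 3e5, cell_conc = 15, syringe_conc = 600,
                       noise_sd = 0.1, seed = 3)
  fit2 <- fit_single_site(sim$titration)
  expect_true(fit2$weak_binding)
})

test_that("thermodynamic decomposition matches the published panel", {
  expect_equal(derive_thermodynamics(41.8, temperature = 15)$dg, -9.73,
               tolerance = 0.005)
  expect_equal(derive_thermodynamics(8.0, temperature = 15)$dg, -10.68,
               tolerance = 0.005)
  expect_equal(derive_thermodynamics(41.8, -11.09, 15)$tds, -1.36,
               tolerance = 0.005)
  # standard state: 1 M dissociation constant has zero free energy
  expect_equal(derive_thermodynamics(1e9, temperature = 15)$dg, 0)
  expect_error(derive_thermodynamics(-1), "positive")
})

test_that("fit identities hold to machine precision", {
  sim <- gen_titration(noise_sd = 0.1, seed = 5)
  fit <- fit_single_site(sim$titration)
  t_k <- fit$temperature + 273.15
  expect_lt(abs(fit$dg - (fit$dh - fit$tds)), 1e-12)
  expect_lt(abs(fit$dg - R_KCAL * t_k * log(fit$kd * 1e-9)), 1e-12)
  expect_equal(fit$c_value, fit$n_sites * 20e-6 / (fit$kd * 1e-9))
})

test_that("decreasing kd steepens the isotherm", {
  kds <- c(1000, 100, 10, 1)
  steep <- vapply(kds, function(kd) {
    sim <- gen_titration(kd = kd, noise_sd = 0, dilution_offset = 0)
    iso <- to_isotherm(sim$titration)
    max(abs(diff(iso$ndh_kcal_per_mol)))
  }, numeric(1))
  expect_true(all(diff(steep) >= 0))
})

test_that("isotherm plateau and degenerate series behave", {
  sim <- gen_titration(kd = 1e-4, dh = -8, noise_sd = 0, dilution_offset = 0)
  iso <- to_isotherm(sim$titration)
  expect_equal(nrow(iso), 38) # control injection excluded
  expect_lt(abs(iso$ndh_kcal_per_mol[2] - (-8)), 0.05)
  zero <- make_titr(heats = rep(0, 39))
  expect_true(all(to_isotherm(zero)$ndh_kcal_per_mol == 0))
  expect_true(all(diff(to_isotherm(zero)$molar_ratio) > 0))
})

test_that("affinity classification bins with inclusive boundaries", {
  expect_equal(classify_affinity(41.8), "<=100 nM")
  expect_equal(classify_affinity(100), "<=100 nM") # boundary to tighter bin
  expect_equal(classify_affinity(4762), "1-10 uM")
  expect_equal(classify_affinity(150.2), "100 nM-1 uM")
  expect_equal(classify_affinity(2e4), ">10 uM")
  expect_equal(classify_affinity(NA, weak = TRUE), "weak")
})
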