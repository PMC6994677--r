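test_that("dividing a scaled form factor returns S identically 1", {
  q <- seq(0.01, 0.2, by = 0.005)
  P <- eval_excluded_volume_form_factor(q, 26.7, 0.55)
  form <- scattering_curve(q, P, concentration = 0)
  conc <- scattering_curve(q, 30 * P, concentration = 30)
  S <- experimental_structure_factor(conc, form)
  expect_lt(max(abs(S$S - 1)), 1e-12)
})

test_that("structure factor round-trips through a hard-sphere product", {
  q <- seq(0.005, 0.35, by = 0.0025)
  radius <- 20
  P <- eval_generalized_guinier(q, 1, 15, 0)
  S_true <- py_hard_sphere_sq(q * 2 * radius, eta = 0.15)
  set.seed(TEST_SEED)
  ideal <- 30 * P * S_true
  sig <- 0.01 * ideal
  conc <- scattering_curve(q, ideal + rnorm(length(q), 0, sig), sig,
                           concentration = 30)
  form <- scattering_curve(q, P, concentration = 0)
  S <- experimental_structure_factor(conc, form, smooth_window = 5)
  rms <- sqrt(mean((S$S / S_true - 1)^2))
  expect_lt(rms, 0.02)
  ## a minimum at q = 0.07 corresponds to a 90 A interaction distance
  qmin <- 0.07
  expect_equal(2 * pi / qmin, 90, tolerance = 0.003)
})

test_that("non-positive form factor is rejected", {
  q <- seq(0.01, 0.1, by = 0.01)
  form <- scattering_curve(q, c(rep(1, 5), -0.1, rep(1, 4)))
  conc <- scattering_curve(q, rep(1, 10), concentration = 30)
  expect_error(experimental_structure_factor(conc, form), "non-positive")
})

test_that("MSA at zero charge equals the Percus-Yevick closed form", {
  qsig <- seq(0.3, 25, length.out = 200)
  for (eta in c(0.05, 0.1, 0.2)) {
    radius <- 20
    p <- msa_params(radius, eta, effective_charge = 0, screening_length = 30)
    S <- eval_msa_sq(qsig / (2 * radius), p)
    expect_lt(max(abs(as.numeric(S) - py_hard_sphere_sq(qsig, eta))), 1e-6)
  }
})

test_that("MSA limits: ideal gas, large q, weak-charge continuity", {
  p0 <- msa_params(20, 1e-4, 0, 30)
  S0 <- eval_msa_sq(seq(0.01, 0.3, by = 0.01), p0)
  expect_lt(max(abs(as.numeric(S0) - 1)), 1e-3)
  ## |S - 1| decays toward 0 well beyond the core scale
  p <- msa_params(20, 0.05, 5, 30)
  qfar <- c(5, 10, 20) / 20
  Sfar <- as.numeric(eval_msa_sq(qfar, p))
  expect_true(all(abs(Sfar - 1) < c(0.15, 0.08, 0.04)))
  ## tiny charge stays close to the hard-sphere solution
  ps <- msa_params(20, 0.1, 0.05, 30)
  qs <- seq(0.01, 0.5, by = 0.01)
  Ssmall <- as.numeric(eval_msa_sq(qs, ps))
  Shs <- py_hard_sphere_sq(qs * 40, 0.1)
  expect_lt(max(abs(Ssmall - Shs)), 5e-3)
})

test_that("charged MSA is repulsive and the rescaled branch is physical", {
  q <- seq(0.005, 0.3, by = 0.005)
  p_hs <- msa_params(20, 0.02, 0, 30)
  p_ch <- msa_params(20, 0.02, 10, 30)
  S_hs <- as.numeric(eval_msa_sq(q, p_hs))
  S_ch <- eval_msa_sq(q, p_ch)
  ## repulsion suppresses low-q concentration fluctuations
  expect_lt(S_ch[1], S_hs[1])
  expect_gte(attr(S_ch, "g_contact"), -1e-3)
  expect_gte(attr(S_ch, "rescale_factor"), 1)
})

test_that("MSA fit recovers self-generated charge and screening length", {
  q <- seq(0.005, 0.25, by = 0.005)
  truth <- msa_params(17, 0.02, 12, 30)
  S_true <- as.numeric(eval_msa_sq(q, truth, grid_points = 512))
  set.seed(TEST_SEED)
  sig <- rep(0.02, length(q))
  S_exp <- structure(list(q = q, S = S_true + rnorm(length(q), 0, sig),
                          sigma = sig, smoothing = "none"),
                     class = "structure_factor_curve")
  init <- msa_params(17, 0.02, 8, 45)
  fit <- fit_msa(S_exp, init)
  expect_lt(abs(fit$params$effective_charge / 12 - 1), 0.10)
  expect_lt(abs(fit$params$screening_length / 30 - 1), 0.10)
})

test_that("MSA fit flags degenerate flat input and bad initial values", {
  q <- seq(0.005, 0.25, by = 0.005)
  S_exp <- structure(list(q = q, S = rep(1, length(q)),
                          sigma = rep(0.01, length(q)), smoothing = "none"),
                     class = "structure_factor_curve")
  init <- msa_params(17, 0.001, 3, 30)
  fit <- fit_msa(S_exp, init)
  expect_true(fit$degenerate || fit$params$effective_charge < 0.5)
  bad_init <- msa_params(17, 0.02, 300, 30)  # charge above the fit bound
  expect_error(fit_msa(S_exp, bad_init), "bounds")
})

test_that("hydrodynamic function estimators reproduce the published table", {
  expect_equal(round(hydrodynamic_function_low_q(1.4, 0.436, 2.5), 3), 0.244)
  expect_equal(hydrodynamic_function_low_q(2.3, 0.615, 2.0), 0.707,
               tolerance = 5e-4)
  expect_equal(hydrodynamic_function_low_q(2.5, 1, 2.5), 1)
  expect_equal(round(hydrodynamic_function_high_q(5.01, 1.72), 3), 0.343)
  expect_equal(round(hydrodynamic_function_high_q(2.83, 1.97), 3), 0.696)
  expect_equal(hydrodynamic_function_high_q(2.2, 2.2), 1)
  ## scale invariance of both estimators
  expect_equal(hydrodynamic_function_low_q(2.8, 0.436, 5.0),
               hydrodynamic_function_low_q(1.4, 0.436, 2.5))
  expect_equal(hydrodynamic_function_high_q(10.02, 3.44),
               hydrodynamic_function_high_q(5.01, 1.72))
})

test_that("Stokes-Einstein radius conversion and scaling laws", {
  const <- nsedyn_constants()
  ## D chosen so that R_H = 20 A at the heavy-water viscosity, 10 degrees C
  D <- const$kB * 283.15 / (6 * pi * 1.679e-3 * 2e-9) * 1e11
  expect_equal(D, 6.18, tolerance = 1e-3)
  expect_equal(stokes_einstein_rh(D, 1.679, 283.15), 20, tolerance = 1e-10)
  expect_equal(stokes_einstein_rh(2 * D, 1.679, 283.15), 10, tolerance = 1e-10)
  expect_equal(stokes_einstein_rh(D, 2 * 1.679, 283.15), 10, tolerance = 1e-10)
})

test_that("physical constants round-trip between unit systems", {
  const <- nsedyn_constants()
  ## D: A^2/ns <-> m^2/s
  expect_equal(1 * const$D_A2ns_per_m2s / (const$A_per_m^2 / const$ns_per_s), 1)
  ## thermal energy over viscosity has A^3/ns scale used by the Zimm times
  x <- nsedyn:::.kbt_over_eta_A3ns(1.7, 283.15)
  expect_equal(x * 1.7e-3 / 1e30 * 1e9, const$kB * 283.15, tolerance = 1e-12)
})
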