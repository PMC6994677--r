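gdmcl_spec <- function(...) {
  zimm_model_spec(N = 20, nu = 0.64, l = 13.4, eta = 1.9,
                  temperature = 283.15, ...)
}

test_that("Zimm relaxation times follow the p^(-3 nu) spectrum", {
  spec <- gdmcl_spec()
  tau <- zimm_relaxation_times(spec)
  p <- seq_along(tau)
  expect_equal(tau / tau[1], p^(-3 * 0.64), tolerance = 1e-12)
  expect_true(all(diff(tau) < 0))
  ## hand evaluation of the closed form for the expanded denatured chain
  expect_equal(tau[1], 120, tolerance = 0.01)
  ## linear in viscosity
  spec2 <- zimm_model_spec(N = 20, nu = 0.64, l = 13.4, eta = 3.8,
                           temperature = 283.15)
  expect_equal(zimm_relaxation_times(spec2), 2 * tau, tolerance = 1e-12)
})

test_that("internal friction shifts every mode time and vanishes in the Zimm limit", {
  tau <- zimm_relaxation_times(gdmcl_spec())
  expect_identical(zif_relaxation_times(tau, 0), tau)
  shifted <- zif_relaxation_times(tau, 50.89)
  expect_equal(shifted - tau, rep(50.89, length(tau)))
  frozen <- zif_relaxation_times(tau, 1e6)
  expect_lt(max(abs(frozen / 1e6 - 1)), 2e-4)
})

test_that("first Zimm time matches mode 1, scales as R_E^3, and has the expected magnitude", {
  spec <- gdmcl_spec()
  expect_equal(first_zimm_time(spec), zimm_relaxation_times(spec)[1])
  spec_big <- zimm_model_spec(N = 20, nu = 0.64, l = 2 * 13.4, eta = 1.9,
                              temperature = 283.15)
  expect_equal(first_zimm_time(spec_big) / first_zimm_time(spec), 8,
               tolerance = 1e-12)
  ## acid-unfolded chain: tens of ns, same order as its internal friction time
  pd2 <- zimm_model_spec(N = 20, nu = 0.55, l = 13.6, eta = 1.7,
                         temperature = 283.15, tau_intern = 50.89)
  t1 <- first_zimm_time(pd2)
  expect_gt(t1, 10); expect_lt(t1, 100)
  expect_lt(abs(log10(t1 / pd2$tau_intern)), 1)
})

test_that("bead-pair correlator matches its printed closed form and a brute-force sum", {
  spec <- zimm_model_spec(N = 3, nu = 0.55, l = 10, eta = 1.7,
                          temperature = 283.15, tau_intern = 5)
  ## static part only at t = 0
  expect_equal(mode_correlator_B(0, 2, 0, spec), 2^(2 * 0.55) * 100)
  expect_equal(mode_correlator_B(1, 1, 0, spec), 0)
  ## symmetric in (n, m)
  expect_equal(mode_correlator_B(0, 2, 7, spec), mode_correlator_B(2, 0, 7, spec))
  ## n = m, all modes relaxed: closed limit
  tau <- zif_relaxation_times(zimm_relaxation_times(spec), 5)
  p <- seq_len(spec$p_max)
  closed <- (4 * spec$R_E^2 / pi^2) *
    sum(p^(-2 * 0.55 - 1) * cos(pi * p * 1 / 3)^2)
  expect_equal(mode_correlator_B(1, 1, 1e9, spec), closed, tolerance = 1e-9)
  ## oracle equivalence on the toy chain
  for (n in 0:2) for (m in 0:2) for (tt in c(0, 1, 10, 100)) {
    expect_equal(mode_correlator_B(n, m, tt, spec),
                 brute_B(n, m, tt, 3, 0.55, 10, spec$R_E, tau),
                 tolerance = 1e-12)
  }
  expect_error(mode_correlator_B(3, 0, 1, spec), "indices")
})

test_that("chain ISF is normalized, matches brute force, and has analytic limits", {
  spec <- zimm_model_spec(N = 4, nu = 0.5, l = 12, eta = 1.7,
                          temperature = 283.15, D = 2, tau_intern = 3,
                          H_over_S = 0.8)
  t <- c(0, 0.5, 2, 10, 50, 200)
  isf <- zimm_isf(0.1, t, spec)
  expect_identical(isf[1], 1)
  tau <- zif_relaxation_times(zimm_relaxation_times(spec), 3)
  oracle <- brute_zimm_isf(0.1, t, 4, 0.5, 12, spec$R_E, tau, 2, 0.8)
  expect_equal(isf, oracle, tolerance = 1e-10)
  ## frozen internal modes leave pure center-of-mass diffusion
  spec_frozen <- zimm_model_spec(N = 4, nu = 0.5, l = 12, eta = 1.7,
                                 temperature = 283.15, D = 2,
                                 tau_intern = 1e14, H_over_S = 0.8)
  isf_frozen <- zimm_isf(0.1, t, spec_frozen)
  expect_equal(isf_frozen, exp(-0.1^2 * 2 * 0.8 * t), tolerance = 1e-6)
})

test_that("ISF invariants: monotone in t, slower with internal friction, Zimm identity", {
  spec0 <- zimm_model_spec(N = 20, nu = 0.55, l = 13.6, eta = 1.7,
                           temperature = 283.15, D = 3, tau_intern = 0)
  spec50 <- zimm_model_spec(N = 20, nu = 0.55, l = 13.6, eta = 1.7,
                            temperature = 283.15, D = 3, tau_intern = 50)
  t <- seq(0, 150, by = 1.5)
  for (q in c(0.05, 0.1, 0.15)) {
    i0 <- zimm_isf(q, t, spec0)
    i50 <- zimm_isf(q, t, spec50)
    expect_true(all(diff(i0) < 1e-12))
    expect_true(all(i50[-1] > i0[-1]))
  }
  ## ZIF with tau_intern = 0 is bit-identical to Zimm
  spec0b <- spec0
  spec0b$tau_intern <- 0
  expect_identical(zimm_isf(0.1, t, spec0), zimm_isf(0.1, t, spec0b))
})

test_that("spectrum simulation is deterministic with q-ordered faster decay", {
  spec <- zimm_model_spec(N = 20, nu = 0.55, l = 13.6, eta = 1.7,
                          temperature = 283.15, D = 3, tau_intern = 50)
  t <- c(0, 2, 5, 10, 20, 50)
  qs <- seq(0.05, 0.15, by = 0.02)
  a <- simulate_spectra(spec, qs, t)
  b <- simulate_spectra(spec, qs, t)
  expect_identical(a$value, b$value)
  ## monotone decays, faster at higher q
  at50 <- a$value[a$t == 50]
  expect_true(all(diff(at50) < 0))
  empty <- simulate_spectra(spec, numeric(0), t)
  expect_equal(nrow(empty), 0)
})

test_that("global ZIF fit is exact on noiseless Zimm data and prefers the true nu", {
  spec_true <- zimm_model_spec(N = 20, nu = 0.64, l = 13.4, eta = 1.9,
                               temperature = 283.15, D = 1.2, tau_intern = 0)
  t <- c(0, exp(seq(log(0.5), log(150), length.out = 20)))
  qs <- seq(0.05, 0.15, by = 0.025)
  data <- simulate_spectra(spec_true, qs, t)
  data$sigma <- rep(0.01, nrow(data))
  start <- spec_true; start$D <- 2; start$tau_intern <- 10
  fit <- fit_zif_global(data, start)
  expect_lt(fit$tau_intern, 0.5)
  expect_equal(fit$D, 1.2, tolerance = 1e-3)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$t_zimm, first_zimm_time(spec_true))
  ## model selection: wrong nu fits worse
  for (dnu in c(-0.1, 0.1)) {
    wrong <- zimm_model_spec(N = 20, nu = 0.64 + dnu, l = 13.4, eta = 1.9,
                             temperature = 283.15, D = 2, tau_intern = 10)
    fitw <- fit_zif_global(data, wrong)
    expect_gt(fitw$chi2, fit$chi2 * 10)
  }
})

test_that("ZIF recovery holds for a longer chain discretization (N = 30)", {
  spec30 <- zimm_model_spec(N = 30, nu = 0.55, l = 13.6 * (20 / 30)^0.55,
                            eta = 1.7, temperature = 283.15, D = 3,
                            tau_intern = 50.89)
  t <- c(0, exp(seq(log(0.5), log(250), length.out = 30)))
  qs <- seq(0.04, 0.15, by = 0.02)
  clean <- simulate_spectra(spec30, qs, t)
  set.seed(TEST_SEED)
  sig <- 0.02 * (1 + clean$t / max(t))
  noisy <- isf_set(clean$q, clean$t, clean$value + rnorm(nrow(clean), 0, sig),
                   sig)
  start <- spec30; start$D <- 2; start$tau_intern <- 10
  fit <- fit_zif_global(noisy, start)
  expect_lt(abs(fit$D / 3 - 1), 0.1)
  expect_lt(abs(fit$tau_intern / 50.89 - 1), 0.15)
})
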