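test_that("ISF files round-trip through both text dialects", {
  t <- seq(0, 50, by = 5)
  isf <- isf_set(q = rep(c(0.05, 0.1), each = length(t)),
                 t = rep(t, 2),
                 value = c(exp(-0.01 * t), exp(-0.04 * t)),
                 sigma = rep(0.01, 2 * length(t)),
                 sample = "roundtrip", temperature = 283.15)
  path <- withr::local_tempfile(fileext = ".dat")
  write_isf(isf, path)
  back <- read_isf(path)
  expect_equal(length(unique(back$q)), 2)
  expect_equal(back$value, isf$value, tolerance = 1e-6)
  expect_equal(attr(back, "sample"), "roundtrip")
  ## flat 4-column dialect
  path2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# temperature = 290",
               apply(cbind(isf$q, isf$t, isf$value, isf$sigma), 1, paste,
                     collapse = " ")), path2)
  back2 <- read_isf(path2)
  expect_equal(back2$value, isf$value)
  expect_equal(attr(back2, "temperature"), 290)
})

test_that("ISF reader converts microseconds and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# t_unit = us", "q = 0.1",
               "0.001 0.9 0.01", "0.002 0.8 0.01"), path)
  isf <- read_isf(path)
  expect_equal(isf$t, c(1, 2))   # converted to ns
  empty <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(0), empty)
  expect_error(read_isf(empty), "no data rows")
  nonmono <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("q = 0.1", "2 0.8 0.01", "1 0.9 0.01"), nonmono)
  expect_error(read_isf(nonmono), "increasing")
  nosigma <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("q = 0.1", "1 0.9", "2 0.8"), nosigma)
  expect_warning(isf2 <- read_isf(nosigma), "sigma")
  expect_equal(isf2$sigma, 0.02 * c(0.9, 0.8))
})

test_that("initial-slope fit recovers a pure exponential exactly", {
  t <- seq(0, 300, by = 10)
  isf <- isf_set(rep(0.1, length(t)), t, exp(-0.01 * t),
                 sigma = rep(0.005, length(t)))
  fit <- fit_initial_slope(isf)
  expect_equal(fit$D1, 0.01, tolerance = 1e-8)
  expect_equal(fit$D2, 0, tolerance = 1e-10)
  expect_equal(fit$A, 1, tolerance = 1e-8)
  expect_false(fit$unphysical)
  ## constant signal has zero first cumulant
  flat <- isf_set(rep(0.1, 10), seq(0, 90, by = 10), rep(1, 10),
                  sigma = rep(0.005, 10))
  expect_equal(fit_initial_slope(flat)$D1, 0, tolerance = 1e-10)
})

test_that("internal chain modes raise the first cumulant above q^2 D_cm", {
  spec <- zimm_model_spec(N = 20, nu = 0.55, l = 13.6, eta = 1.7,
                          temperature = 283.15, D = 3.0, tau_intern = 50)
  t <- seq(0, 60, by = 2)
  isf <- simulate_spectra(spec, q = 0.12, t = t)
  fit <- fit_initial_slope(isf)
  expect_gt(fit$D1, 3.0 * 0.12^2)
})

test_that("stretched-exponential fit is exact on single exponentials", {
  t <- seq(1, 120, by = 4)
  isf <- isf_set(rep(0.1, length(t)), t, exp(-2.5 * 0.1^2 * t),
                 sigma = rep(0.01, length(t)))
  fit <- fit_stretched_exponential(isf)
  expect_equal(fit$beta, 1, tolerance = 0.01)
  expect_equal(fit$Dprime, 2.5, tolerance = 0.01)
  ## beta = 0.85 synthetic input is recovered within 0.02
  isf2 <- isf_set(rep(0.1, length(t)), t, exp(-2.5 * 0.1^2 * t^0.85),
                  sigma = rep(0.01, length(t)))
  fit2 <- fit_stretched_exponential(isf2)
  expect_equal(fit2$beta, 0.85, tolerance = 0.02)
  ## cumulant and stretched fits agree on single-exponential input
  cum <- fit_initial_slope(isf)
  expect_equal(cum$D1, fit$Dprime * 0.1^2, tolerance = 0.01)
})

test_that("doubling all uncertainties doubles the parameter standard errors", {
  t <- seq(0, 60, by = 4)
  y <- exp(-0.02 * t)
  isf1 <- isf_set(rep(0.1, length(t)), t, y, sigma = rep(0.01, length(t)))
  isf2 <- isf_set(rep(0.1, length(t)), t, y, sigma = rep(0.02, length(t)))
  f1 <- fit_initial_slope(isf1)
  f2 <- fit_initial_slope(isf2)
  expect_equal(f2$D1_se / f1$D1_se, 2, tolerance = 1e-6)
  s1 <- fit_stretched_exponential(isf_set(rep(0.1, length(t)), t, y,
                                          sigma = rep(0.01, length(t))))
  s2 <- fit_stretched_exponential(isf_set(rep(0.1, length(t)), t, y,
                                          sigma = rep(0.02, length(t))))
  expect_equal(s2$beta_se / s1$beta_se, 2, tolerance = 1e-6)
})

test_that("effective diffusion applies the S/H correction as D1/q^2 * S/H", {
  t <- seq(0, 80, by = 4)
  qs <- c(0.06, 0.1, 0.14)
  D <- 2.0
  isf <- isf_set(rep(qs, each = length(t)), rep(t, 3),
                 unlist(lapply(qs, function(q) exp(-D * q^2 * t))),
                 sigma = rep(0.005, 3 * length(t)))
  cum <- fit_initial_slope(isf)
  deff <- suppressWarnings(effective_diffusion(cum, NULL, H_q0 = 1))
  expect_equal(deff$D_eff, rep(D, 3), tolerance = 1e-6)
  expect_equal(deff$D_eff, cum$D1 / cum$q^2, tolerance = 1e-12)
  ## a structure factor and H rescale the result
  Sq <- structure(list(q = qs, S = c(0.5, 0.6, 0.7), sigma = rep(0, 3),
                       smoothing = "none"), class = "structure_factor_curve")
  deff2 <- effective_diffusion(cum, Sq, H_q0 = 0.25)
  expect_equal(deff2$D_eff, D * c(0.5, 0.6, 0.7) / 0.25, tolerance = 1e-6)
  expect_error(effective_diffusion(cum, Sq, H_q0 = 0), "positive")
})

test_that("linearity diagnostic distinguishes Zimm-like from flat curves", {
  exact <- structure(data.frame(q = seq(0.05, 0.15, 0.01),
                                D_eff = 1 + 10 * seq(0.05, 0.15, 0.01),
                                sigma = 0.01),
                     class = c("effective_diffusion_curve", "data.frame"))
  lin <- linearity_diagnostic(exact)
  expect_equal(lin$r_squared, 1, tolerance = 1e-12)
  expect_equal(lin$slope, 10, tolerance = 1e-10)
  flat <- exact; flat$D_eff <- rep(2, nrow(flat))
  expect_equal(linearity_diagnostic(flat)$slope, 0, tolerance = 1e-12)
  ## Zimm-model spectra give a positive, strongly linear D_eff(q)
  spec <- zimm_model_spec(N = 20, nu = 0.64, l = 13.4, eta = 1.9,
                          temperature = 283.15, D = 1.2)
  t <- c(0, exp(seq(log(0.5), log(120), length.out = 25)))
  isf <- simulate_spectra(spec, q = seq(0.06, 0.15, by = 0.01), t = t)
  deff <- suppressWarnings(effective_diffusion(fit_initial_slope(isf)))
  zl <- linearity_diagnostic(deff)
  expect_gt(zl$slope, 0)
  expect_gt(zl$r_squared, 0.95)
})
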