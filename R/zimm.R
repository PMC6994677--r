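#' Specification of a Zimm / ZIF chain model
#'
#' Full parameterization of the bead-spring dynamic structure factor used
#' to model NSE spectra of unfolded protein chains: a finite chain of `N`
#' beads with Kuhn length `l` and Flory exponent `nu`, relaxing through
#' hydrodynamically coupled normal modes with relaxation times
#' \eqn{\tau_p = \eta R_E^3 / (\sqrt{3\pi}\, k_B T)\; p^{-3\nu}}, plus
#' optional mode-independent internal friction (`tau_intern`, the ZIF
#' model) added to every mode time, and center-of-mass diffusion `D`
#' corrected by the hydrodynamic-function/structure-factor ratio
#' `H_over_S`.
#'
#' The default center-of-mass diffusion coefficient follows the Zimm
#' relation \eqn{D = 0.196\, k_B T / (\eta R_E)}, making the chain a
#' single self-consistent Zimm object; supply `D` explicitly (e.g. from
#' DLS) to override.
#'
#' @param N number of beads (default 20).
#' @param nu Flory exponent.
#' @param l Kuhn length (A).  Give either `l` or `Rg`.
#' @param Rg radius of gyration (A); used to derive `l` via the
#'   freely-jointed-chain relation when `l` is missing.
#' @param eta solvent viscosity (mPa s).
#' @param temperature temperature (K).
#' @param p_max number of normal modes (default `N`).
#' @param mode_amplitudes amplitudes A(p), length `p_max`; all 1 for the
#'   Zimm and ZIF models.
#' @param tau_intern internal friction time (ns, >= 0); 0 is the plain
#'   Zimm model.
#' @param D center-of-mass diffusion coefficient (A^2/ns); default from
#'   the Zimm relation.
#' @param H_over_S hydrodynamic-function over structure-factor correction
#'   applied to the center-of-mass term (default 1).
#' @param tau_prefactor dimensionless prefactor of the first relaxation
#'   time; default \eqn{1/\sqrt{3\pi}} (standard Zimm with excluded
#'   volume).  Exposed for sensitivity checks.
#' @return Object of class `zimm_model_spec`.
#' @examples
#' spec <- zimm_model_spec(nu = 0.55, l = 13.6, eta = 1.7,
#'                         temperature = 283.15, D = 3.0, tau_intern = 50.89)
#' first_zimm_time(spec)
#' @export
zimm_model_spec <- function(N = 20, nu, l = NULL, Rg = NULL, eta,
                            temperature = 283.15, p_max = N,
                            mode_amplitudes = rep(1, p_max),
                            tau_intern = 0, D = NULL, H_over_S = 1,
                            tau_prefactor = 1 / sqrt(3 * pi)) {
  .assert(N >= 2, "N must be >= 2")
  .assert(nu >= 0.3 && nu <= 1, "nu must lie in [0.3, 1]")
  .assert(!is.null(l) || !is.null(Rg), "give either l or Rg")
  if (is.null(l)) l <- kuhn_length(Rg, nu, N)
  .assert(l > 0, "Kuhn length must be positive")
  .assert(eta > 0 && temperature > 0, "eta and temperature must be positive")
  .assert(p_max >= 1 && p_max <= N, "p_max must lie in [1, N]")
  .assert(length(mode_amplitudes) == p_max, "mode_amplitudes must have length p_max")
  .assert(tau_intern >= 0, "tau_intern must be >= 0")
  R_E <- l * N^nu
  if (!is.null(Rg)) {
    ## consistency of (nu, l, N) with Rg within 1%
    re_rg <- end_to_end(Rg, nu)
    .assert(abs(re_rg - R_E) / R_E < 0.01 + 1e-12,
            "R_E from (nu, l, N) and from Rg disagree by more than 1%")
  }
  if (is.null(D)) D <- 0.196 * .kbt_over_eta_A3ns(eta, temperature) / R_E
  .assert(D > 0, "D must be positive")
  .assert(H_over_S > 0, "H_over_S must be positive")
  structure(list(N = N, nu = nu, l = l, R_E = R_E, eta = eta,
                 temperature = temperature, p_max = p_max,
                 mode_amplitudes = mode_amplitudes,
                 tau_intern = tau_intern, D = D, H_over_S = H_over_S,
                 tau_prefactor = tau_prefactor),
            class = "zimm_model_spec")
}

#' @export
print.zimm_model_spec <- function(x, ...) {
  cat(sprintf("Zimm%s chain: N = %d, nu = %.2f, l = %.2f A, R_E = %.1f A, eta = %.2f mPa s, T = %.2f K\n",
              if (x$tau_intern > 0) " + internal friction" else "",
              x$N, x$nu, x$l, x$R_E, x$eta, x$temperature))
  cat(sprintf("  D = %.3f A^2/ns, tau_intern = %.2f ns, p_max = %d, H/S = %.3f, tau_1 = %.1f ns\n",
              x$D, x$tau_intern, x$p_max, x$H_over_S, first_zimm_time(x)))
  invisible(x)
}

#' Zimm mode relaxation times
#'
#' \eqn{\tau_p = c_\tau\, \eta R_E^3 / (k_B T)\; p^{-3\nu}} for modes
#' p = 1..p_max, with the prefactor \eqn{c_\tau = 1/\sqrt{3\pi}} by
#' default.  The spectrum is strictly decreasing in p.
#'
#' @param spec a [zimm_model_spec].
#' @return Vector of relaxation times in ns, one per mode.
#' @export
zimm_relaxation_times <- function(spec) {
  .assert(inherits(spec, "zimm_model_spec"), "spec must be a zimm_model_spec")
  tau1 <- spec$tau_prefactor * spec$R_E^3 /
    .kbt_over_eta_A3ns(spec$eta, spec$temperature)
  tau1 * seq_len(spec$p_max)^(-3 * spec$nu)
}

#' Add internal friction to a Zimm mode spectrum
#'
#' The ZIF model adds a mode-independent internal friction time to every
#' Zimm relaxation time: \eqn{\tau_p^{ZIF} = \tau_p + \tau_{intern}},
#' which damps the high-frequency modes.
#'
#' @param tau_p Zimm relaxation times (ns).
#' @param tau_intern internal friction time (ns, >= 0).
#' @return Elementwise sum.
#' @export
zif_relaxation_times <- function(tau_p, tau_intern) {
  .assert(tau_intern >= 0, "tau_intern must be >= 0")
  tau_p + tau_intern
}

#' First Zimm relaxation time
#'
#' Relaxation time of the slowest internal mode (p = 1) of the underlying
#' Zimm spectrum, before any internal-friction shift.  Scales as
#' \eqn{R_E^3}.
#'
#' @param spec a [zimm_model_spec].
#' @return \eqn{\tau_1} in ns.
#' @export
first_zimm_time <- function(spec) {
  zimm_relaxation_times(spec)[1]
}

#' Bead-pair displacement correlator of the chain model
#'
#' Evaluates, for bead indices n and m (0-based, 0..N-1),
#' \deqn{B(n,m,t) = |n-m|^{2\nu} l^2 + \frac{4 R_E^2}{\pi^2}
#'   \sum_{p=1}^{p_{max}} \frac{A(p)}{p^{2\nu+1}}
#'   \cos\!\frac{\pi p n}{N}\cos\!\frac{\pi p m}{N}
#'   \left[1 - e^{-t/\tau_p}\right]}
#' with \eqn{\tau_p} the (ZIF-shifted, when `tau_intern > 0`) mode times.
#' Symmetric in (n, m); at t = 0 only the static part survives.
#'
#' @param n,m bead indices in 0..N-1 (scalars).
#' @param t time(s) in ns (vector allowed).
#' @param spec a [zimm_model_spec].
#' @return B in A^2, same length as `t`.
#' @export
mode_correlator_B <- function(n, m, t, spec) {
  .assert(inherits(spec, "zimm_model_spec"), "spec must be a zimm_model_spec")
  .assert(n >= 0 && n < spec$N && m >= 0 && m < spec$N,
          "bead indices must lie in 0..N-1")
  .assert(all(t >= 0), "t must be >= 0")
  p <- seq_len(spec$p_max)
  tau <- zif_relaxation_times(zimm_relaxation_times(spec), spec$tau_intern)
  static <- abs(n - m)^(2 * spec$nu) * spec$l^2
  coef <- (4 * spec$R_E^2 / pi^2) * spec$mode_amplitudes / p^(2 * spec$nu + 1) *
    cos(pi * p * n / spec$N) * cos(pi * p * m / spec$N)
  vapply(t, function(tt) {
    static + sum(coef * (1 - exp(-tt / tau)))
  }, numeric(1))
}

## B matrices for all bead pairs at each time; internal vectorized core.
## Returns list(Bstat = NxN static matrix, Bt = function(t) NxN matrix).
.zimm_B_engine <- function(spec) {
  N <- spec$N
  n <- 0:(N - 1)
  p <- seq_len(spec$p_max)
  tau <- zif_relaxation_times(zimm_relaxation_times(spec), spec$tau_intern)
  Bstat <- outer(n, n, function(a, b) abs(a - b)^(2 * spec$nu)) * spec$l^2
  Cmat <- cos(pi * outer(p, n) / N)                  # p_max x N
  wstat <- spec$mode_amplitudes / p^(2 * spec$nu + 1)
  pref <- 4 * spec$R_E^2 / pi^2
  list(
    Bstat = Bstat,
    Bt = function(tt) {
      wp <- wstat * (1 - exp(-tt / tau))
      Bstat + pref * crossprod(Cmat, wp * Cmat)
    }
  )
}

#' Normalized Zimm / ZIF intermediate scattering function
#'
#' Dynamic structure factor of the bead-spring chain,
#' \deqn{I(q,t) = \frac{e^{-q^2 D (H/S) t}}{N}
#'   \sum_{n,m} \exp\!\left[-\frac{q^2 B(n,m,t)}{6}\right],}
#' returned normalized as \eqn{I(q,t)/I(q,0)} (NSE measures normalized
#' ISFs).  With all internal modes frozen
#' (\eqn{\tau_{intern} \to \infty}) the decay reduces to pure
#' center-of-mass diffusion \eqn{\exp[-q^2 D (H/S) t]}.
#'
#' @param q momentum transfer (1/A), positive scalar.
#' @param t times (ns), vector.
#' @param spec a [zimm_model_spec].
#' @return Normalized ISF values, same length as `t`; exactly 1 at t = 0.
#' @examples
#' spec <- zimm_model_spec(nu = 0.5, l = 14, eta = 1.7)
#' zimm_isf(0.1, c(0, 10, 50), spec)
#' @export
zimm_isf <- function(q, t, spec) {
  .assert(inherits(spec, "zimm_model_spec"), "spec must be a zimm_model_spec")
  .assert(.is_number(q) && q > 0, "q must be a positive scalar")
  .assert(all(t >= 0), "t must be >= 0")
  eng <- .zimm_B_engine(spec)
  i0 <- mean(exp(-q^2 * eng$Bstat / 6))
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    com <- exp(-q^2 * spec$D * spec$H_over_S * tt)
    com * mean(exp(-q^2 * eng$Bt(tt) / 6)) / i0
  }, numeric(1))
}

#' Simulate noiseless NSE spectra from a chain model
#'
#' Evaluates [zimm_isf] on a (q, t) grid and packs the result as an
#' [isf_set] with zero uncertainties.
#'
#' @param spec a [zimm_model_spec].
#' @param q momentum transfers (1/A), vector (may be empty).
#' @param t Fourier-time grid (ns).
#' @param sample label stored in the output.
#' @return An [isf_set] (zero rows if `q` is empty).
#' @export
simulate_spectra <- function(spec, q, t, sample = "simulated") {
  .assert(inherits(spec, "zimm_model_spec"), "spec must be a zimm_model_spec")
  if (length(q) == 0) {
    return(isf_set(numeric(0), numeric(0), numeric(0), numeric(0),
                   sample = sample, temperature = spec$temperature))
  }
  vals <- unlist(lapply(q, function(qq) zimm_isf(qq, t, spec)))
  isf_set(q = rep(q, each = length(t)), t = rep(t, length(q)),
          value = vals, sigma = rep(0, length(q) * length(t)),
          sample = sample, temperature = spec$temperature)
}

#' Global ZIF fit of NSE spectra
#'
#' Simultaneous weighted least squares of the ZIF dynamic structure factor
#' over all (q, t) points of an ISF set, with the chain parameters
#' (nu, l, N, eta, T, H/S) frozen at the values in `spec` and only the
#' center-of-mass diffusion coefficient D and the internal friction time
#' tau_intern free.  tau_intern is bounded below by 0, so a chain without
#' internal friction (plain Zimm) comes out with tau_intern at the bound.
#'
#' @param data an [isf_set] with at least 2 q values and uncertainties.
#' @param spec a [zimm_model_spec] carrying the frozen parameters and the
#'   start values for D and tau_intern.
#' @return Object of class `zif_fit_result` with fields `D` (A^2/ns),
#'   `tau_intern` (ns), `t_zimm` (first Zimm time of the underlying
#'   spectrum, computed from the spec, not fitted), `chi2` (reduced, over
#'   all jointly fitted points), `covariance` (2x2 for D, tau_intern),
#'   `per_q` (data.frame of per-q RMS residuals), `spec` (the input spec
#'   with fitted values filled in).
#' @export
fit_zif_global <- function(data, spec) {
  .assert(inherits(data, "isf_set"), "data must be an isf_set")
  .assert(inherits(spec, "zimm_model_spec"), "spec must be a zimm_model_spec")
  qs <- unique(data$q)
  .assert(length(qs) >= 2, "need at least 2 q values for a global fit")
  sig <- .clean_sigma(data$sigma)
  ## engine rebuilt once per tau_intern; B(t) cached per unique time
  tgrid <- sort(unique(data$t))
  model_all <- function(D, tau_intern) {
    sp <- spec
    sp$tau_intern <- tau_intern
    sp$D <- D
    eng <- .zimm_B_engine(sp)
    Bt <- lapply(tgrid, eng$Bt)
    names(Bt) <- as.character(tgrid)
    unlist(lapply(qs, function(qq) {
      i0 <- mean(exp(-qq^2 * eng$Bstat / 6))
      tt <- data$t[data$q == qq]
      vapply(tt, function(t1) {
        if (t1 == 0) return(1)
        exp(-qq^2 * D * sp$H_over_S * t1) *
          mean(exp(-qq^2 * Bt[[as.character(t1)]] / 6)) / i0
      }, numeric(1))
    }))
  }
  resid <- function(p) (model_all(p[1], p[2]) - data$value) / sig
  fit <- minpack.lm::nls.lm(par = c(D = spec$D, tau_intern = max(spec$tau_intern, 1)),
                            fn = resid,
                            lower = c(1e-4, 0), upper = c(1e3, 1e4),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info %in% c(0, 9)) {
    stop("global ZIF fit did not converge: ", fit$message,
         "; parameter trace: ", paste(round(fit$par, 4), collapse = ", "),
         call. = FALSE)
  }
  npts <- nrow(data)
  chi2 <- fit$deviance / max(npts - 2, 1)
  res_vec <- fit$fvec
  idx <- rep(qs, times = vapply(qs, function(qq) sum(data$q == qq), integer(1)))
  per_q <- data.frame(q = qs,
                      rms_residual = vapply(qs, function(qq)
                        sqrt(mean(res_vec[idx == qq]^2)), numeric(1)))
  sp_out <- spec
  sp_out$D <- unname(fit$par[1])
  sp_out$tau_intern <- unname(fit$par[2])
  structure(list(D = unname(fit$par[1]),
                 tau_intern = unname(fit$par[2]),
                 t_zimm = first_zimm_time(spec),
                 chi2 = chi2,
                 covariance = .nlslm_cov(fit, 2),
                 per_q = per_q,
                 spec = sp_out),
            class = "zif_fit_result")
}

#' @export
print.zif_fit_result <- function(x, ...) {
  cat(sprintf("ZIF global fit: D = %.3f A^2/ns, tau_intern = %.2f ns, t_Zimm = %.2f ns, chi2 = %.3f\n",
              x$D, x$tau_intern, x$t_zimm, x$chi2))
  invisible(x)
}
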