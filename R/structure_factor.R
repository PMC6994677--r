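#' Experimental structure factor by curve division
#'
#' Divides the per-unit-mass scattering of a concentrated solution by the
#' form factor measured at (or extrapolated to) infinite dilution:
#' \eqn{S(c, q) = [I(q,c)/c] / [P(q)]}.  Both curves are brought to a
#' per-unit-mass scale using their `concentration` metadata (curves with
#' `concentration = 0` are assumed to be per unit mass already), the form
#' factor is interpolated onto the q grid of the concentrated curve over
#' the common q range, and the ratio is smoothed with a centered moving
#' average.  Uncertainties are propagated in quadrature and reduced by the
#' effective averaging window.
#'
#' @param high_c [scattering_curve] of the concentrated solution.
#' @param form [scattering_curve] holding the form factor (per unit mass if
#'   `concentration = 0`, otherwise divided by its concentration).
#' @param smooth_window centered moving-average window in points
#'   (default 5; 1 disables smoothing).
#' @return Object of class `structure_factor_curve`: list with `q`, `S`,
#'   `sigma`, `smoothing` fields.
#' @examples
#' q <- seq(0.01, 0.2, by = 0.005)
#' P <- eval_excluded_volume_form_factor(q, 26.7, 0.55)
#' form <- scattering_curve(q, P, concentration = 0)
#' conc <- scattering_curve(q, 30 * P, concentration = 30)
#' range(experimental_structure_factor(conc, form)$S)  # identically 1
#' @export
experimental_structure_factor <- function(high_c, form, smooth_window = 5) {
  .assert(inherits(high_c, "scattering_curve") && inherits(form, "scattering_curve"),
          "inputs must be scattering_curve objects")
  qlo <- max(min(high_c$q), min(form$q))
  qhi <- min(max(high_c$q), max(form$q))
  .assert(qlo < qhi, "curves have no overlapping q range")
  sel <- high_c$q >= qlo & high_c$q <= qhi
  q <- high_c$q[sel]
  chc <- if (high_c$concentration > 0) high_c$concentration else 1
  cff <- if (form$concentration > 0) form$concentration else 1
  Ihc <- high_c$intensity[sel] / chc
  shc <- high_c$sigma[sel] / chc
  Iff <- .interp_curve(form$q, form$intensity, q) / cff
  sff <- .interp_curve(form$q, .clean_sigma(form$sigma), q) / cff
  if (any(Iff <= 0)) {
    stop("form factor is non-positive inside the common q range", call. = FALSE)
  }
  S <- Ihc / Iff
  sigma <- abs(S) * sqrt((shc / Ihc)^2 + (sff / Iff)^2)
  Ssm <- .moving_average(S, smooth_window)
  neff <- .moving_average_n(length(S), smooth_window)
  sigma_sm <- .moving_average(sigma, smooth_window) / sqrt(neff)
  structure(list(q = q, S = Ssm, sigma = sigma_sm,
                 smoothing = sprintf("centered moving average, %d points",
                                     smooth_window)),
            class = "structure_factor_curve")
}

#' @export
print.structure_factor_curve <- function(x, ...) {
  cat(sprintf("structure_factor_curve: %d points, q = [%.3g, %.3g] 1/A, S(qmin) = %.3f (%s)\n",
              length(x$q), min(x$q), max(x$q), x$S[1], x$smoothing))
  invisible(x)
}

#' @export
as.data.frame.structure_factor_curve <- function(x, ...) {
  data.frame(q = x$q, S = x$S, sigma = x$sigma)
}

#' Hydrodynamic function estimate in the low-q limit
#'
#' \eqn{H_{c,q0} = D_c S_{q0} / D_0}: the collective diffusion coefficient
#' measured at concentration c, corrected by the structure factor at the
#' DLS q value, relative to the infinite-dilution diffusion coefficient.
#'
#' @param D_c collective diffusion coefficient at concentration c (A^2/ns).
#' @param S_q0 structure factor at the DLS q value (dimensionless).
#' @param D_0 diffusion coefficient extrapolated to infinite dilution
#'   (A^2/ns).
#' @return \eqn{H_{c,q0}}, dimensionless.
#' @examples
#' hydrodynamic_function_low_q(1.4, 0.436, 2.5)  # 0.244
#' @export
hydrodynamic_function_low_q <- function(D_c, S_q0, D_0) {
  .assert(D_c > 0 && S_q0 > 0 && D_0 > 0, "all inputs must be positive")
  D_c * S_q0 / D_0
}

#' Hydrodynamic function estimate in the high-q limit
#'
#' Approximated by the viscosity ratio \eqn{H_{c,qL} = \eta_{c=0} /
#' \eta_{conc}} between the dilute and the concentrated protein solution.
#'
#' @param eta_conc viscosity of the concentrated solution (mPa s).
#' @param eta_dilute viscosity of the dilute solution (mPa s).
#' @return \eqn{H_{c,qL}}, dimensionless.
#' @examples
#' hydrodynamic_function_high_q(5.01, 1.72)  # 0.344
#' @export
hydrodynamic_function_high_q <- function(eta_conc, eta_dilute) {
  .assert(eta_conc > 0 && eta_dilute > 0, "viscosities must be positive")
  eta_dilute / eta_conc
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' \eqn{R_H = k_B T / (6 \pi \eta D)}.
#'
#' @param D translational diffusion coefficient (A^2/ns).
#' @param eta solvent viscosity (mPa s).
#' @param temperature temperature (K).
#' @return Hydrodynamic radius in A.
#' @examples
#' stokes_einstein_rh(6.18, 1.679, 283.15)  # about 20 A
#' @export
stokes_einstein_rh <- function(D, eta, temperature) {
  .assert(D > 0 && eta > 0 && temperature > 0, "all inputs must be positive")
  const <- nsedyn_constants()
  D_si <- D / const$D_A2ns_per_m2s            # m^2/s
  eta_si <- eta * const$PaS_per_mPaS          # Pa s
  r_m <- const$kB * temperature / (6 * pi * eta_si * D_si)
  r_m * const$A_per_m
}
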