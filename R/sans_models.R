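#' Generalized Guinier model
#'
#' Evaluates \eqn{I(q) = A \exp[-R_g^2 q^2 / (3-\alpha)]}.  The shape
#' parameter \eqn{\alpha} interpolates between the standard Guinier law for
#' globular particles (\eqn{\alpha = 0}) and elongated/flattened shapes;
#' the model is meaningful for \eqn{q R_g < 1.3}.
#'
#' @param q momentum transfer (1/A), vector.
#' @param A forward-scattering amplitude.
#' @param Rg radius of gyration (A), positive.
#' @param alpha dimensionless shape parameter, must satisfy `alpha < 3`.
#' @return Intensity vector, same length as `q`.
#' @examples
#' eval_generalized_guinier(0.05, A = 1, Rg = 14.8, alpha = 0)
#' @export
eval_generalized_guinier <- function(q, A, Rg, alpha = 0) {
  .assert(Rg > 0, "Rg must be positive")
  if (alpha >= 3) stop("invalid shape parameter: alpha must be < 3", call. = FALSE)
  A * exp(-Rg^2 * q^2 / (3 - alpha))
}

#' Form factor of a polymer chain with excluded volume
#'
#' Normalized form factor \eqn{P(q)} of a flexible chain with Flory
#' (excluded-volume) exponent \eqn{\nu}, in the standard two-term
#' lower-incomplete-gamma representation with reduced variable
#' \eqn{U = q^2 R_g^2 (2\nu+1)(2\nu+2)/6}:
#' \deqn{P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma(1/2\nu, U)
#'            - \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U).}
#' At \eqn{\nu = 1/2} this reduces exactly to the Debye function of a
#' Gaussian chain; the high-q power law is \eqn{q^{-1/\nu}}.
#'
#' @param q momentum transfer (1/A), vector.
#' @param Rg radius of gyration (A), positive.
#' @param nu Flory exponent, in `[0.3, 1]`.
#' @return \eqn{P(q)} with \eqn{P(0) = 1}.
#' @examples
#' eval_excluded_volume_form_factor(c(0, 0.05, 0.1), Rg = 70.2, nu = 0.64)
#' @export
eval_excluded_volume_form_factor <- function(q, Rg, nu) {
  .assert(Rg > 0, "Rg must be positive")
  if (nu < 0.3 || nu > 1) {
    stop("nu out of the supported range [0.3, 1]", call. = FALSE)
  }
  U <- q^2 * Rg^2 * (2 * nu + 1) * (2 * nu + 2) / 6
  a1 <- 1 / (2 * nu)
  a2 <- 1 / nu
  P <- numeric(length(U))
  small <- U < 1e-8
  ## series limit around U = 0 avoids 0^0 and cancellation
  P[small] <- 1 - U[small] * (a1 / (a1 + 1) * 2 - a2 / (a2 + 1))
  u <- U[!small]
  ## lower incomplete gamma via pgamma: gamma(a, u) = pgamma(u, a) * Gamma(a)
  t1 <- (1 / nu) * u^(-a1) * stats::pgamma(u, a1) * gamma(a1)
  t2 <- (1 / nu) * u^(-a2) * stats::pgamma(u, a2) * gamma(a2)
  P[!small] <- t1 - t2
  P
}

#' Flory exponent from the Porod exponent
#'
#' The high-q power-law decay \eqn{I \propto q^{-m}} of a swollen chain is
#' the reciprocal of the excluded-volume exponent: \eqn{\nu = 1/m}.
#'
#' @param m Porod exponent, positive.
#' @return \eqn{\nu = 1/m}.
#' @examples
#' nu_from_porod(1.83)  # 0.55 at two decimals
#' @export
nu_from_porod <- function(m) {
  .assert(all(m > 0), "Porod exponent must be positive")
  1 / m
}

#' Kuhn length of an equivalent freely jointed chain
#'
#' Inverts \eqn{R_g^2 = l^2 N^{2\nu} / [(2\nu+1)(2\nu+2)]} for the
#' statistical segment (Kuhn) length \eqn{l} given the bead count \eqn{N}.
#'
#' @param Rg radius of gyration (A), positive.
#' @param nu Flory exponent.
#' @param N number of beads (>= 2).
#' @return Kuhn length in A.
#' @examples
#' kuhn_length(70.2, 0.64, 20)  # 28.2 A
#' @export
kuhn_length <- function(Rg, nu, N) {
  .assert(Rg > 0, "Rg must be positive")
  .assert(N >= 1, "N must be >= 1")
  Rg * sqrt((2 * nu + 1) * (2 * nu + 2)) / N^nu
}

#' End-to-end distance of an excluded-volume chain
#'
#' \eqn{R_E = \sqrt{(2\nu+1)(2\nu+2)}\, R_g}; equals \eqn{\sqrt{6} R_g}
#' for a Gaussian chain.
#'
#' @param Rg radius of gyration (A), positive.
#' @param nu Flory exponent.
#' @return End-to-end distance in A.
#' @export
end_to_end <- function(Rg, nu) {
  .assert(Rg > 0, "Rg must be positive")
  sqrt((2 * nu + 1) * (2 * nu + 2)) * Rg
}

#' Compactness report from hydrodynamic and gyration radii
#'
#' The ratio \eqn{R_H/R_g} classifies how compact a species is: the
#' theoretical solid-sphere limit is \eqn{(5/3)^{1/2} \approx 1.29}, a
#' random-coil polymer averages about 0.65.
#'
#' @param R_H hydrodynamic radius (A), positive.
#' @param Rg radius of gyration (A), positive.
#' @return Object of class `compactness_report` with fields
#'   `hydrodynamic_radius`, `radius_of_gyration`, `ratio`,
#'   `reference_sphere_limit` and `reference_random_coil`.
#' @examples
#' compactness(19.6, 14.8)$ratio  # 1.32: close to a solid sphere
#' @export
compactness <- function(R_H, Rg) {
  .assert(R_H > 0 && Rg > 0, "radii must be positive")
  structure(list(hydrodynamic_radius = R_H,
                 radius_of_gyration = Rg,
                 ratio = R_H / Rg,
                 reference_sphere_limit = sqrt(5 / 3),
                 reference_random_coil = 0.65),
            class = "compactness_report")
}

#' @export
print.compactness_report <- function(x, ...) {
  cat(sprintf("R_H/Rg = %.3f  (solid sphere %.2f, random coil %.2f)\n",
              x$ratio, x$reference_sphere_limit, x$reference_random_coil))
  invisible(x)
}

#' Overlap concentration of a polymer solution
#'
#' \eqn{c^* = M / (N_A \cdot \frac{4}{3}\pi R_g^3)}: the concentration at
#' which chain coils begin to interpenetrate, separating the dilute from
#' the semidilute regime.
#'
#' @param M molar mass in g/mol.
#' @param Rg radius of gyration; angstrom by default.
#' @param Rg_unit `"A"` (default) or `"nm"`.
#' @return Overlap concentration in g/L.
#' @examples
#' overlap_concentration(16951, 2, Rg_unit = "nm")  # 840 g/L
#' @export
overlap_concentration <- function(M, Rg, Rg_unit = c("A", "nm")) {
  Rg_unit <- match.arg(Rg_unit)
  .assert(M > 0 && Rg > 0, "M and Rg must be positive")
  if (Rg_unit == "nm") Rg <- Rg * 10
  const <- nsedyn_constants()
  vol_L <- (4 / 3) * pi * (Rg * 1e-10)^3 * 1000   # sphere volume in litres
  M / (const$N_A * vol_L)
}

#' Normalized Kratky-Porod representation
#'
#' Transforms a curve to dimensionless coordinates \eqn{x = qR_g},
#' \eqn{y = (qR_g)^2 I(q)/I_0}.  A Gaussian chain plateaus at \eqn{y = 2}
#' at large \eqn{x}; a globular particle shows a single interior maximum.
#'
#' @param curve a [scattering_curve].
#' @param Rg radius of gyration (A), positive.
#' @param I0 forward scattering used for normalization, positive.
#' @return `data.frame` with columns `x`, `y` and `sigma_y`.
#' @export
kratky_transform <- function(curve, Rg, I0) {
  .assert(inherits(curve, "scattering_curve"), "not a scattering_curve")
  .assert(Rg > 0 && I0 > 0, "Rg and I0 must be positive")
  x <- curve$q * Rg
  data.frame(x = x, y = x^2 * curve$intensity / I0,
             sigma_y = x^2 * curve$sigma / I0)
}
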