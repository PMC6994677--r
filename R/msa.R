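#' Parameters of the MSA structure-factor model
#'
#' Parameter set for the mean spherical approximation (MSA) structure
#' factor of charged spheres interacting through a hard core plus a
#' screened-Coulomb (Yukawa) tail, the standard model for macro-ion
#' solutions.
#'
#' @param sphere_radius hard-core radius in A, positive.
#' @param volume_fraction sphere volume fraction, in (0, 0.74).
#' @param effective_charge effective (renormalized) charge in elementary
#'   charges; 0 gives a plain hard-sphere fluid.
#' @param screening_length Debye screening length in A, positive.
#' @param temperature temperature in K.
#' @param dielectric relative dielectric constant of the solvent
#'   (default 85, heavy water near 283 K).
#' @return Object of class `msa_params`.
#' @examples
#' msa_params(17, 0.02, 10, 30)
#' @export
msa_params <- function(sphere_radius, volume_fraction, effective_charge,
                       screening_length, temperature = 283.15,
                       dielectric = 85) {
  .assert(sphere_radius > 0, "sphere_radius must be positive")
  .assert(volume_fraction > 0 && volume_fraction < 0.74,
          "volume_fraction must lie in (0, 0.74)")
  .assert(screening_length > 0, "screening_length must be positive")
  .assert(temperature > 0 && dielectric > 0,
          "temperature and dielectric must be positive")
  structure(list(sphere_radius = sphere_radius,
                 volume_fraction = volume_fraction,
                 effective_charge = effective_charge,
                 screening_length = screening_length,
                 temperature = temperature,
                 dielectric = dielectric),
            class = "msa_params")
}

#' @export
print.msa_params <- function(x, ...) {
  cat(sprintf("MSA parameters: R = %.1f A, phi = %.4f, Z = %.2f e, screening = %.1f A, T = %.1f K, eps = %.0f\n",
              x$sphere_radius, x$volume_fraction, x$effective_charge,
              x$screening_length, x$temperature, x$dielectric))
  invisible(x)
}

## dimensionless contact potential beta*u(sigma+) of the DLVO/Yukawa tail
.msa_contact_potential <- function(params) {
  sigma <- 2 * params$sphere_radius
  lb <- .bjerrum_length(params$temperature, params$dielectric)
  kappa_a <- params$sphere_radius / params$screening_length
  params$effective_charge^2 * lb / (sigma * (1 + kappa_a)^2)
}

## Ornstein-Zernike solver with the MSA closure for a hard core plus
## Yukawa tail, in reduced units (sigma = 1).  Returns S on the requested
## reduced grid qsig = q*sigma together with the contact value g(1+).
##
## eta: volume fraction; gek: contact potential beta*u(sigma+); k: kappa*sigma.
## Picard iteration on gamma = h - c with sine transforms; the hard-core
## discontinuity is grid-aligned and the contact bin carries the mean of
## the inside/outside limits, which makes the scheme O(dr^2) accurate.
.oz_msa_solve <- function(eta, gek, k, qsig, M = 1024, rmax = NULL,
                          tol = 1e-12, maxit = 20000) {
  if (is.null(rmax)) rmax <- min(max(64, ceiling(1 + 25 / max(k, 0.4))), 256)
  dr <- 1 / M
  N <- round(rmax * M)
  r <- (1:(N - 1)) * dr
  kj <- pi * (1:(N - 1)) / rmax
  rho <- 6 * eta / pi
  icontact <- M
  core <- seq_len(N - 1) < icontact
  ctail <- -gek * exp(-k * (r - 1)) / r
  dst <- function(x) { z <- c(0, x, 0, -rev(x)); -Im(stats::fft(z))[2:N] / 2 }
  build_c <- function(gam) {
    cr <- ctail
    cr[core] <- -1 - gam[core]
    cr[icontact] <- 0.5 * ((-1 - gam[icontact]) + ctail[icontact])
    cr
  }
  gam <- numeric(N - 1)
  cr <- build_c(gam)
  mix <- 0.6
  converged <- FALSE
  for (it in seq_len(maxit)) {
    chat <- 4 * pi * dr * dst(r * cr) / kj
    denom <- 1 - rho * chat
    if (any(denom <= 0)) stop("OZ iteration lost stability (S(q) diverged)",
                              call. = FALSE)
    ghat <- rho * chat^2 / denom
    gnew <- (pi / rmax) / (2 * pi^2 * r) * dst(ghat * kj)
    del <- max(abs(gnew - gam))
    gam <- mix * gnew + (1 - mix) * gam
    cr <- build_c(gam)
    if (del < tol) { converged <- TRUE; break }
  }
  if (!converged) stop("OZ/MSA iteration did not converge", call. = FALSE)
  ## g(1+) = 1 + gamma(1) + c(1+)
  g_contact <- 1 + gam[icontact] + ctail[icontact]
  ## output S: Simpson quadrature over the smooth core + analytic tail
  g0 <- gam[1] - (gam[2] - gam[1])
  rcore <- c(0, r[1:icontact])
  ccore <- c(-1 - g0, -1 - gam[1:icontact])
  ## Simpson weights (npt = M + 1 is odd since M is even)
  npt <- length(rcore)
  w <- rep(c(4, 2), length.out = npt - 1)
  w <- c(1, w[-(npt - 1)], 1) / 3 * dr
  S <- vapply(qsig, function(q) {
    x <- q * rcore
    sinc <- ifelse(x < 1e-8, 1 - x^2 / 6, sin(x) / x)
    chat_core <- 4 * pi * sum(w * rcore^2 * ccore * sinc)
    chat_tail <- if (gek != 0) {
      -4 * pi * (gek / q) * (k * sin(q) + q * cos(q)) / (k^2 + q^2)
    } else 0
    1 / (1 - rho * (chat_core + chat_tail))
  }, numeric(1))
  list(S = S, g_contact = g_contact, iterations = it)
}

#' MSA structure factor for charged spheres
#'
#' Structure factor of a one-component fluid of charged hard spheres with
#' a screened-Coulomb (Yukawa) repulsion in the mean spherical
#' approximation, computed by numerically solving the Ornstein-Zernike
#' equation under the MSA closure (direct correlation function equal to
#' minus the reduced pair potential outside the core, zero pair
#' correlation inside).  At zero charge the model is the Percus-Yevick
#' hard-sphere fluid.
#'
#' When the MSA yields an unphysical negative contact value of the pair
#' correlation function, the standard rescaling is applied: the hard core
#' is inflated (at fixed number density and potential) until the contact
#' value vanishes, which leaves the physics unchanged because the true
#' core is never approached in such weakly coupled systems.
#'
#' @param q momentum transfer (1/A), vector, positive.
#' @param params an [msa_params] object.
#' @param grid_points radial grid points per hard-core diameter
#'   (default 1024; accuracy is O(1/grid_points^2)).
#' @param rescale apply contact-value rescaling when needed (default TRUE).
#' @return S(q) vector; attributes `g_contact` (contact value of g after
#'   any rescaling) and `rescale_factor` (effective-to-true diameter
#'   ratio, 1 when no rescaling was needed).
#' @examples
#' \donttest{
#' p <- msa_params(20, 0.05, 0, 30)
#' S <- eval_msa_sq(seq(0.01, 0.5, by = 0.01), p)
#' }
#' @export
eval_msa_sq <- function(q, params, grid_points = 1024, rescale = TRUE) {
  .assert(inherits(params, "msa_params"), "params must be msa_params")
  .assert(all(q > 0), "q must be positive")
  sigma <- 2 * params$sphere_radius
  eta <- params$volume_fraction
  k <- sigma / params$screening_length
  gek <- .msa_contact_potential(params)
  solve_at <- function(s) {
    ## s = effective/true diameter ratio; rescaled reduced parameters
    .oz_msa_solve(eta * s^3, gek * exp(-k * (s - 1)) / s, k * s,
                  q * sigma * s, M = grid_points)
  }
  sol <- solve_at(1)
  sfac <- 1
  if (rescale && sol$g_contact < -1e-4) {
    ## inflate the effective core until g(contact) >= 0, then root-find;
    ## the effective packing fraction is capped where the solver is stable
    smax <- (0.5 / eta)^(1 / 3)
    gfun <- function(s) .oz_msa_solve(eta * s^3, gek * exp(-k * (s - 1)) / s,
                                      k * s, 1, M = 256)$g_contact
    lo <- 1
    hi <- min(1.2, smax)
    found <- FALSE
    while (hi <= smax + 1e-12) {
      if (gfun(hi) >= 0) { found <- TRUE; break }
      lo <- hi
      hi <- min(hi * 1.2, smax)
      if (hi <= lo + 1e-9) break
    }
    if (!found) {
      stop("unphysical MSA contact value and no rescaling possible",
           call. = FALSE)
    }
    sfac <- stats::uniroot(gfun, c(lo, hi), tol = 1e-4)$root
    sol <- solve_at(sfac)
  }
  out <- sol$S
  attr(out, "g_contact") <- sol$g_contact
  attr(out, "rescale_factor") <- sfac
  out
}

#' Fit the MSA structure factor to an experimental curve
#'
#' Bounded weighted least squares of [eval_msa_sq] against an experimental
#' structure factor, with a chosen subset of the parameters frozen at
#' their initial values.
#'
#' @param S_exp a `structure_factor_curve` (see
#'   [experimental_structure_factor]) with at least 10 points.
#' @param init an [msa_params] object with the start values.
#' @param frozen character vector of field names to keep fixed; default
#'   frees `effective_charge` and `screening_length` only.
#' @param grid_points radial resolution passed to [eval_msa_sq]
#'   (default 512 for speed during fitting).
#' @return List of class `msa_fit` with fields `params` (fitted
#'   [msa_params]), `chi2` (reduced), `covariance` (free parameters) and
#'   `degenerate` (TRUE when the charge collapsed to its lower bound).
#' @export
fit_msa <- function(S_exp, init,
                    frozen = c("sphere_radius", "volume_fraction",
                               "temperature", "dielectric"),
                    grid_points = 512) {
  .assert(inherits(S_exp, "structure_factor_curve"),
          "S_exp must be a structure_factor_curve")
  .assert(length(S_exp$q) >= 10, "need at least 10 points to fit the MSA")
  .assert(inherits(init, "msa_params"), "init must be msa_params")
  all_fields <- c("sphere_radius", "volume_fraction", "effective_charge",
                  "screening_length", "temperature", "dielectric")
  free <- setdiff(all_fields, frozen)
  .assert(length(free) >= 1, "at least one parameter must be free")
  lower_all <- c(sphere_radius = 1, volume_fraction = 1e-5,
                 effective_charge = 0, screening_length = 1,
                 temperature = 1, dielectric = 1)
  upper_all <- c(sphere_radius = 1e3, volume_fraction = 0.7,
                 effective_charge = 200, screening_length = 1e4,
                 temperature = 1e3, dielectric = 200)
  p0 <- unlist(init[free])
  if (any(p0 < lower_all[free] - 1e-12) || any(p0 > upper_all[free] + 1e-12)) {
    stop("initial parameters outside the fit bounds", call. = FALSE)
  }
  sig <- .clean_sigma(S_exp$sigma)
  make_params <- function(p) {
    cur <- init
    for (nm in free) cur[[nm]] <- unname(p[nm])
    cur
  }
  resid <- function(p) {
    cur <- make_params(p)
    S <- tryCatch(eval_msa_sq(S_exp$q, cur, grid_points = grid_points),
                  error = function(e) rep(1e6, length(S_exp$q)))
    (as.numeric(S) - S_exp$S) / sig
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            lower = lower_all[free], upper = upper_all[free],
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10))
  if (fit$info %in% c(0, 9)) {
    warning("MSA fit did not converge: ", fit$message)
  }
  dof <- max(length(S_exp$q) - length(free), 1)
  structure(list(params = make_params(fit$par),
                 chi2 = fit$deviance / dof,
                 covariance = .nlslm_cov(fit, length(free)) *
                   fit$deviance / dof,
                 degenerate = "effective_charge" %in% free &&
                   fit$par["effective_charge"] < 1e-3,
                 convergence_info = fit$info),
            class = "msa_fit")
}
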