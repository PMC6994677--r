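#' Initial-slope (cumulant) fit of NSE spectra
#'
#' Fits, independently at every q, the two-term cumulant form
#' \eqn{S(q,t)/S(q,0) = A \exp(-D_1 t - D_2 t^2)} to the initial decay of
#' the normalized ISF.  The fit window keeps the times where the signal
#' has decayed by less than a fraction of its amplitude
#' (`decay_window_fraction`, default: points with \eqn{S/S_0 \ge 0.4}).
#' \eqn{D_1} is the first cumulant in 1/ns; divide by \eqn{q^2} (done by
#' [effective_diffusion]) to obtain a diffusion coefficient in
#' \eqn{\mathrm{\AA^2/ns}}.
#'
#' @param isf an [isf_set].
#' @param decay_window_fraction keep times with value >= this fraction of
#'   the fitted amplitude (default 0.4).
#' @return Object of class `cumulant_fit`: a `data.frame` with one row per
#'   q (`q`, `A`, `D1`, `D1_se`, `D2`, `n_points`, `t_max`, `unphysical`)
#'   and attribute `covariances` (list of 3x3 matrices).
#' @examples
#' t <- seq(0, 60, by = 4)
#' isf <- isf_set(rep(0.1, length(t)), t, exp(-0.01 * t),
#'                sigma = rep(0.01, length(t)))
#' fit_initial_slope(isf)$D1  # 0.01 1/ns
#' @export
fit_initial_slope <- function(isf, decay_window_fraction = 0.4) {
  .assert(inherits(isf, "isf_set"), "not an isf_set")
  .assert(decay_window_fraction > 0 && decay_window_fraction < 1,
          "decay_window_fraction must be in (0,1)")
  qs <- unique(isf$q)
  out <- list()
  covs <- list()
  for (qq in qs) {
    sub <- isf[isf$q == qq, ]
    A0 <- sub$value[1]
    sel <- sub$value >= decay_window_fraction * A0
    if (sum(sel) < 5) sel <- seq_len(nrow(sub)) <= min(5, nrow(sub))
    .assert(sum(sel) >= 5,
            sprintf("fewer than 5 points in the initial-slope window at q = %g", qq))
    tt <- sub$t[sel]; yy <- sub$value[sel]
    ss <- .clean_sigma(sub$sigma[sel])
    ## log-linear start for D1
    pos <- yy > 0
    d1_0 <- if (sum(pos) >= 2) {
      max(-stats::coef(stats::lm(log(yy[pos]) ~ tt[pos]))[2], 1e-6)
    } else 1e-3
    resid <- function(p) (p[1] * exp(-p[2] * tt - p[3] * tt^2) - yy) / ss
    fit <- minpack.lm::nls.lm(par = c(A = min(max(A0, 0.8), 1.2),
                                      D1 = unname(d1_0), D2 = 0),
                              fn = resid,
                              lower = c(0.8, -Inf, -Inf),
                              upper = c(1.2, Inf, Inf),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    dof <- max(sum(sel) - 3, 1)
    cov <- .nlslm_cov(fit, 3)
    covs[[as.character(qq)]] <- cov
    out[[length(out) + 1]] <- data.frame(
      q = qq, A = fit$par[1], D1 = fit$par[2],
      D1_se = sqrt(abs(cov[2, 2])), D2 = fit$par[3],
      n_points = sum(sel), t_max = max(tt),
      unphysical = fit$par[2] < 0)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cumulant_fit", "data.frame"), covariances = covs)
}

#' Stretched-exponential (Kohlrausch-Williams-Watts) fit of NSE spectra
#'
#' Fits, at every q, \eqn{S(q,t)/S(q,0) = A \exp[-(D' q^2 t^{\beta})]}.
#' The stretching exponent \eqn{\beta} is bounded to `[0.3, 1.2]` and
#' initialized at 0.85; \eqn{\beta = 1} is simple diffusion, and a broad
#' distribution of internal relaxation modes pushes \eqn{\beta} below 1
#' (the Zimm prediction for a Gaussian chain in solution is about 0.85).
#' Note that the exponent acts on t only, so the unit of \eqn{D'} depends
#' on the fitted \eqn{\beta} (\eqn{\mathrm{\AA^2/ns^\beta}}).
#'
#' @param isf an [isf_set].
#' @param beta_bounds lower/upper bounds for the stretching exponent.
#' @return Object of class `stretched_fit`: `data.frame` with one row per
#'   q (`q`, `A`, `Dprime`, `beta`, `beta_se`, `at_bound`) and attribute
#'   `mean_beta` (unweighted mean over q).
#' @examples
#' t <- seq(1, 80, by = 4)
#' isf <- isf_set(rep(0.1, length(t)), t, exp(-2 * 0.01 * t^0.85),
#'                sigma = rep(0.01, length(t)))
#' attr(fit_stretched_exponential(isf), "mean_beta")
#' @export
fit_stretched_exponential <- function(isf, beta_bounds = c(0.3, 1.2)) {
  .assert(inherits(isf, "isf_set"), "not an isf_set")
  qs <- unique(isf$q)
  out <- list()
  for (qq in qs) {
    sub <- isf[isf$q == qq, ]
    .assert(nrow(sub) >= 6,
            sprintf("need at least 6 points per q (q = %g)", qq))
    tt <- sub$t; yy <- sub$value
    ss <- .clean_sigma(sub$sigma)
    pos <- tt > 0
    y1 <- yy[pos][1]; t1 <- tt[pos][1]
    d0 <- max(-log(max(y1, 1e-8)) / (qq^2 * t1^0.85), 1e-8)
    resid <- function(p) {
      (p[1] * exp(-exp(p[2]) * qq^2 * tt^p[3]) - yy) / ss
    }
    fit <- minpack.lm::nls.lm(par = c(A = 1, logD = log(d0), beta = 0.85),
                              fn = resid,
                              lower = c(0.8, -30, beta_bounds[1]),
                              upper = c(1.2, 15, beta_bounds[2]),
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    dof <- max(nrow(sub) - 3, 1)
    cov <- .nlslm_cov(fit, 3)
    beta <- unname(fit$par[3])
    out[[length(out) + 1]] <- data.frame(
      q = qq, A = unname(fit$par[1]), Dprime = exp(unname(fit$par[2])),
      beta = beta, beta_se = sqrt(abs(cov[3, 3])),
      at_bound = beta <= beta_bounds[1] + 1e-6 ||
        beta >= beta_bounds[2] - 1e-6)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$at_bound)) {
    warning("stretching exponent pinned at a bound for some q")
  }
  structure(res, class = c("stretched_fit", "data.frame"),
            mean_beta = mean(res$beta))
}

#' Effective diffusion coefficients corrected for interactions
#'
#' Converts first cumulants to diffusion coefficients and applies the
#' interaction corrections:
#' \eqn{D_{eff}(q) = [D_1(q)/q^2] \; S(c,q) / H_{c,q0}}, with the
#' structure factor interpolated at each fitted q and the hydrodynamic
#' function treated as a q-independent constant.
#'
#' @param cumulants a `cumulant_fit` from [fit_initial_slope].
#' @param S_cq optional `structure_factor_curve`; default uses
#'   \eqn{S \equiv 1} (with a warning, since the correction is then
#'   incomplete for concentrated samples).
#' @param H_q0 hydrodynamic function (positive scalar, default 1).
#' @return Object of class `effective_diffusion_curve`: `data.frame` with
#'   `q`, `D_eff` (A^2/ns), `sigma`.
#' @export
effective_diffusion <- function(cumulants, S_cq = NULL, H_q0 = 1) {
  .assert(inherits(cumulants, "cumulant_fit"), "cumulants must be a cumulant_fit")
  if (H_q0 <= 0) stop("H_q0 must be positive", call. = FALSE)
  q <- cumulants$q
  if (is.null(S_cq)) {
    warning("no structure factor supplied: assuming S(c,q) = 1")
    Sq <- rep(1, length(q)); Ssig <- rep(0, length(q))
  } else {
    .assert(inherits(S_cq, "structure_factor_curve"),
            "S_cq must be a structure_factor_curve")
    Sq <- .interp_curve(S_cq$q, S_cq$S, q)
    Ssig <- .interp_curve(S_cq$q, S_cq$sigma, q)
  }
  D <- (cumulants$D1 / q^2) * Sq / H_q0
  rel <- sqrt((cumulants$D1_se / pmax(abs(cumulants$D1), 1e-12))^2 +
                (Ssig / Sq)^2)
  res <- data.frame(q = q, D_eff = D, sigma = abs(D) * rel)
  structure(res, class = c("effective_diffusion_curve", "data.frame"))
}

#' Linearity diagnostic for the Zimm regime
#'
#' Ordinary least squares of \eqn{D_{eff}} on q.  A linear increase of the
#' effective diffusion coefficient with q is the signature of Zimm-type
#' local chain relaxation; a flat curve indicates center-of-mass diffusion
#' of a compact particle.
#'
#' @param curve an `effective_diffusion_curve`.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linearity_diagnostic <- function(curve) {
  .assert(inherits(curve, "effective_diffusion_curve"),
          "curve must be an effective_diffusion_curve")
  .assert(nrow(curve) >= 4, "need at least 4 points")
  fit <- stats::lm(D_eff ~ q, data = curve)
  ## summary() warns on numerically perfect fits; those are valid input here
  ss <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = ss$r.squared)
}
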