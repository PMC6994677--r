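#' Fit a form-factor model to a SANS curve
#'
#' Weighted least squares (weights \eqn{1/\sigma^2}; zero uncertainties are
#' replaced by the median positive one) of either the generalized Guinier
#' model or the excluded-volume polymer form factor.
#'
#' For `model = "guinier"` the fit window is iterated: starting from the
#' supplied window the upper bound is shrunk until
#' \eqn{q_{max} R_g \le 1.3} (at most 10 iterations), enforcing the
#' validity range of the Guinier expansion.
#'
#' For `model = "excluded_volume"` the parameters are an overall amplitude,
#' \eqn{R_g} and the Flory exponent \eqn{\nu} (bounded to `[0.3, 1]`); the
#' returned object also carries the derived chain quantities (Porod
#' exponent \eqn{m = 1/\nu}, Kuhn length for `N` beads, end-to-end
#' distance).
#'
#' @param curve a [scattering_curve].
#' @param model `"guinier"` or `"excluded_volume"`.
#' @param q_window numeric length-2 `c(qmin, qmax)` restricting the fit;
#'   default uses the whole curve.
#' @param N bead count used to derive the Kuhn length (excluded-volume
#'   model only).
#' @param start optional named list of start values (`A`, `Rg`, `alpha`
#'   or `A`, `Rg`, `nu`).
#' @param fix_alpha for the Guinier model, fix the shape parameter at this
#'   value instead of fitting it (default 0, the standard Guinier law);
#'   use `NULL` to fit alpha.
#' @return For `"guinier"` an object of class `guinier_fit` with fields
#'   `amplitude`, `radius_of_gyration`, `shape_parameter`, `valid_qmax`,
#'   `covariance`, `valid`.  For `"excluded_volume"` an object of class
#'   `polymer_chain_fit` with `amplitude`, `radius_of_gyration`,
#'   `flory_exponent`, `porod_exponent`, `kuhn_length`, `end_to_end`,
#'   `n_beads`, `covariance`.
#' @examples
#' q <- seq(0.01, 0.08, by = 0.002)
#' crv <- scattering_curve(q, eval_generalized_guinier(q, 1, 15, 0),
#'                         sigma = rep(1e-4, length(q)))
#' fit_form_factor(crv, "guinier")$radius_of_gyration
#' @export
fit_form_factor <- function(curve, model = c("guinier", "excluded_volume"),
                            q_window = NULL, N = 20, start = NULL,
                            fix_alpha = 0) {
  model <- match.arg(model)
  .assert(inherits(curve, "scattering_curve"), "not a scattering_curve")
  q <- curve$q; I <- curve$intensity
  sig <- .clean_sigma(curve$sigma)
  if (is.null(q_window)) q_window <- range(q)
  sel <- q >= q_window[1] & q <= q_window[2]
  .assert(sum(sel) >= 5, "need at least 5 points inside the fit window")

  if (model == "guinier") {
    .fit_guinier(q, I, sig, sel, start, fix_alpha)
  } else {
    .fit_excluded_volume(q, I, sig, sel, start, N)
  }
}

.fit_guinier <- function(q, I, sig, sel, start, fix_alpha) {
  fit_once <- function(sel) {
    qs <- q[sel]; ys <- I[sel]; ss <- sig[sel]
    i0 <- max(ys[1], 1e-12)
    ## slope of log I vs q^2 for the Rg start value
    sl <- stats::coef(stats::lm(log(pmax(ys, 1e-12)) ~ I(qs^2)))[2]
    rg0 <- sqrt(max(-3 * sl, 1e-4))
    p0 <- c(A = i0, Rg = rg0)
    if (is.null(fix_alpha)) p0 <- c(p0, alpha = 0)
    if (!is.null(start)) p0[names(start)] <- unlist(start)
    resid <- function(p) {
      al <- if (is.null(fix_alpha)) p[3] else fix_alpha
      if (al >= 2.99) al <- 2.99
      (p[1] * exp(-p[2]^2 * qs^2 / (3 - al)) - ys) / ss
    }
    lower <- c(0, 0); upper <- c(Inf, Inf)
    if (is.null(fix_alpha)) { lower <- c(lower, 0); upper <- c(upper, 2) }
    minpack.lm::nls.lm(par = p0, fn = resid, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- fit_once(sel)
  ## shrink the window until qmax * Rg <= 1.3
  for (i in seq_len(10)) {
    rg <- fit$par[2]
    qmax <- max(q[sel])
    if (qmax * rg <= 1.3 || sum(sel) <= 5) break
    sel_new <- sel & q <= 1.3 / rg
    if (sum(sel_new) < 5) sel_new <- sel & (cumsum(sel) <= 5)
    sel <- sel_new
    fit <- fit_once(sel)
  }
  if (fit$info %in% c(0, 9)) {
    stop("Guinier fit did not converge: ", fit$message, call. = FALSE)
  }
  rg <- fit$par[2]
  npar <- length(fit$par)
  dof <- max(sum(sel) - npar, 1)
  cov <- .nlslm_cov(fit, npar)
  valid <- rg > 0.5 && max(q[sel]) * rg <= 1.3 + 1e-9
  structure(list(amplitude = unname(fit$par[1]),
                 radius_of_gyration = unname(rg),
                 shape_parameter = if (is.null(fix_alpha)) unname(fit$par[3]) else fix_alpha,
                 valid_qmax = max(q[sel]),
                 covariance = cov,
                 chi2 = fit$deviance / dof,
                 valid = valid,
                 n_points = sum(sel)),
            class = "guinier_fit")
}

.fit_excluded_volume <- function(q, I, sig, sel, start, N) {
  qs <- q[sel]; ys <- I[sel]; ss <- sig[sel]
  ## data-driven starts: nu from the high-q log-log slope, Rg from a
  ## Guinier estimate on the low-q quarter of the window
  pos <- ys > 0
  nu0 <- 0.55
  hi <- pos & qs >= stats::quantile(qs[pos], 0.6)
  if (sum(hi) >= 3) {
    m_est <- -stats::coef(stats::lm(log(ys[hi]) ~ log(qs[hi])))[2]
    if (is.finite(m_est) && m_est > 0) nu0 <- min(max(1 / m_est, 0.31), 0.99)
  }
  lo <- pos & qs <= stats::quantile(qs[pos], 0.25)
  rg0 <- 2 / max(qs[1], 1e-3)
  if (sum(lo) >= 3) {
    sl <- stats::coef(stats::lm(log(ys[lo]) ~ I(qs[lo]^2)))[2]
    if (is.finite(sl) && sl < 0) rg0 <- sqrt(-3 * sl)
  }
  p0 <- c(A = max(ys[1], 1e-12), Rg = rg0, nu = nu0)
  if (!is.null(start)) p0[names(start)] <- unlist(start)
  resid <- function(p) {
    (p[1] * eval_excluded_volume_form_factor(qs, p[2], p[3]) - ys) / ss
  }
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            lower = c(0, 1, 0.3), upper = c(Inf, 1e4, 1),
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  if (fit$info %in% c(0, 9)) {
    stop("excluded-volume fit did not converge: ", fit$message, call. = FALSE)
  }
  dof <- max(sum(sel) - 3, 1)
  cov <- .nlslm_cov(fit, 3)
  rg <- unname(fit$par[2]); nu <- unname(fit$par[3])
  structure(list(amplitude = unname(fit$par[1]),
                 radius_of_gyration = rg,
                 flory_exponent = nu,
                 porod_exponent = 1 / nu,
                 kuhn_length = kuhn_length(rg, nu, N),
                 end_to_end = end_to_end(rg, nu),
                 n_beads = N,
                 covariance = cov,
                 chi2 = fit$deviance / dof,
                 n_points = sum(sel)),
            class = "polymer_chain_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: A = %.4g, Rg = %.3f A (alpha = %.2f), qmax*Rg = %.2f%s\n",
              x$amplitude, x$radius_of_gyration, x$shape_parameter,
              x$valid_qmax * x$radius_of_gyration,
              if (x$valid) "" else "  [INVALID]"))
  invisible(x)
}

#' @export
print.polymer_chain_fit <- function(x, ...) {
  cat(sprintf("excluded-volume chain: Rg = %.2f A, nu = %.3f (m = %.2f), l = %.2f A (N = %d), R_E = %.1f A\n",
              x$radius_of_gyration, x$flory_exponent, x$porod_exponent,
              x$kuhn_length, x$n_beads, x$end_to_end))
  invisible(x)
}

#' Extrapolate concentration series to infinite dilution
#'
#' Performs, at every q point, a weighted linear fit of \eqn{I(q,c)/c}
#' versus \eqn{c} and returns the intercept: the form factor per unit
#' mass, free of interparticle interference.  Curves are interpolated
#' linearly onto the q grid of the first curve (restricted to the common
#' q range) when grids differ.
#'
#' @param curves list of [scattering_curve] objects at different (positive)
#'   concentrations.
#' @return A [scattering_curve] with `concentration = 0` whose intensity is
#'   the per-unit-mass form factor and whose sigma is the standard error of
#'   the intercept.  With a single input curve, returns `I/c` unchanged
#'   with a warning.
#' @export
extrapolate_infinite_dilution <- function(curves) {
  .assert(is.list(curves) && length(curves) >= 1 &&
            all(vapply(curves, inherits, logical(1), "scattering_curve")),
          "curves must be a list of scattering_curve objects")
  conc <- vapply(curves, `[[`, numeric(1), "concentration")
  .assert(all(conc > 0), "all curves need a positive concentration")
  if (length(curves) == 1) {
    warning("single concentration supplied: returning I/c without extrapolation")
    cur <- curves[[1]]
    return(scattering_curve(cur$q, cur$intensity / conc,
                            cur$sigma / conc, concentration = 0,
                            temperature = cur$temperature,
                            label = paste0(cur$label, " (pass-through)")))
  }
  qlo <- max(vapply(curves, function(x) min(x$q), numeric(1)))
  qhi <- min(vapply(curves, function(x) max(x$q), numeric(1)))
  .assert(qlo < qhi, "curves have no overlapping q range")
  qout <- curves[[1]]$q[curves[[1]]$q >= qlo & curves[[1]]$q <= qhi]
  Imat <- vapply(curves, function(x) .interp_curve(x$q, x$intensity, qout),
                 numeric(length(qout)))
  Smat <- vapply(curves, function(x) {
    .interp_curve(x$q, .clean_sigma(x$sigma), qout)
  }, numeric(length(qout)))
  inter <- se <- numeric(length(qout))
  for (i in seq_along(qout)) {
    y <- Imat[i, ] / conc
    ## weights from the supplied uncertainties; covariance is the plain
    ## (X' W X)^{-1} so that the intercept error propagates the input sigmas
    w <- (conc / Smat[i, ])^2
    X <- cbind(1, conc)
    XtWX <- crossprod(X, w * X)
    cov <- solve(XtWX)
    beta <- cov %*% crossprod(X, w * y)
    inter[i] <- beta[1]
    se[i] <- sqrt(cov[1, 1])
  }
  scattering_curve(qout, inter, se, concentration = 0,
                   temperature = curves[[1]]$temperature,
                   label = "extrapolated to infinite dilution")
}
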