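#' Study-condition parameter sets for the four folding states
#'
#' Returns the full parameterization of one of the four apomyoglobin-like
#' folding states used throughout the synthetic-data generators: the
#' native-like state at pD 6, the molten globule at pD 4, the acid
#' unfolded state at pD 2 and the GdmCl-denatured state.  Structural
#' parameters (Rg, Flory exponent or Guinier shape, hydrodynamic radius),
#' dynamical parameters (center-of-mass D, internal friction time,
#' solvent viscosity, dynamical Kuhn length) and the scalar side
#' measurements (structure factor at the DLS q value, concentrated /
#' dilute viscosities, DLS diffusion coefficients) are the published
#' working values for these states; noise levels default to 2% relative
#' for SANS and absolute sigma0 = 0.02 for the ISF.
#'
#' @param name one of `"pd6"`, `"pd4"`, `"pd2"`, `"gdmcl"`.
#' @param seed integer seed stored with the state; mandatory for any
#'   stochastic generator output.
#' @param sans_noise relative SANS noise level (default 0.02).
#' @param isf_sigma0 absolute ISF noise at t = 0 (default 0.02; grows
#'   linearly to twice that at the longest Fourier time).
#' @return Object of class `sample_state_spec`: nested list with
#'   `name`, `seed`, `structural`, `dynamical`, `scalars`, `noise`.
#' @examples
#' st <- sample_state_spec("pd2", seed = 1)
#' st$dynamical$D           # 3.0 A^2/ns
#' st$dynamical$tau_intern  # 50.89 ns
#' @export
sample_state_spec <- function(name = c("pd6", "pd4", "pd2", "gdmcl"),
                              seed, sans_noise = 0.02, isf_sigma0 = 0.02) {
  name <- match.arg(name)
  .assert(.is_number(seed), "a numeric seed is mandatory")
  tab <- list(
    pd6 = list(
      structural = list(Rg = 14.8, alpha = 0, R_H = 19.6, model = "guinier"),
      dynamical = list(D = 6.1, tau_intern = NA_real_, eta = 1.7,
                       l = NA_real_, nu = NA_real_),
      scalars = list(S_q0 = 1.163, D_conc = 6.1, D_0 = 8.2,
                     eta_conc = 2.2, eta_dilute = 1.70)),
    pd4 = list(
      structural = list(Rg = 25.4, nu = 0.46, R_H = 30.0,
                        model = "excluded_volume"),
      dynamical = list(D = 1.7, tau_intern = 49.63, eta = 1.7, l = 15.1,
                       nu = 0.46),
      scalars = list(S_q0 = 0.436, D_conc = 1.4, D_0 = 2.5,
                     eta_conc = 5.01, eta_dilute = 1.72)),
    pd2 = list(
      structural = list(Rg = 26.7, nu = 0.55, R_H = 18.0,
                        model = "excluded_volume"),
      dynamical = list(D = 3.0, tau_intern = 50.89, eta = 1.7, l = 13.6,
                       nu = 0.55),
      scalars = list(S_q0 = 0.485, D_conc = 6.0, D_0 = 3.8,
                     eta_conc = NA_real_, eta_dilute = 1.74)),
    gdmcl = list(
      structural = list(Rg = 70.2, nu = 0.64, R_H = 56.7,
                        model = "excluded_volume"),
      dynamical = list(D = 1.2, tau_intern = 0, eta = 1.9, l = 13.4,
                       nu = 0.64),
      scalars = list(S_q0 = 0.615, D_conc = 2.3, D_0 = 2.0,
                     eta_conc = 2.83, eta_dilute = 1.97))
  )
  st <- tab[[name]]
  structure(list(name = name, seed = as.integer(seed),
                 structural = st$structural, dynamical = st$dynamical,
                 scalars = st$scalars, temperature = 283.15,
                 noise = list(sans_rel = sans_noise, isf_sigma0 = isf_sigma0)),
            class = "sample_state_spec")
}

#' @export
print.sample_state_spec <- function(x, ...) {
  cat(sprintf("sample_state_spec '%s' (seed %d): Rg = %.1f A, R_H = %.1f A, D = %.2f A^2/ns\n",
              x$name, x$seed, x$structural$Rg, x$structural$R_H,
              x$dynamical$D))
  invisible(x)
}

## Zimm/ZIF chain spec from a sample state (unfolded states only)
.state_zimm_spec <- function(state) {
  dyn <- state$dynamical
  .assert(!is.na(dyn$nu), "no chain model for the native-like state")
  zimm_model_spec(N = 20, nu = dyn$nu, l = dyn$l, eta = dyn$eta,
                  temperature = state$temperature,
                  tau_intern = dyn$tau_intern, D = dyn$D)
}

#' Generate a synthetic SANS concentration series
#'
#' Emulates background-corrected SANS curves
#' \eqn{I(q,c) = c \, P(q) \, S(q,c) + \epsilon}: the state's form factor
#' (excluded-volume chain for denatured states, generalized Guinier for
#' the native-like state) times a concentration-dependent structure
#' factor, plus seeded Gaussian noise of the state's relative amplitude.
#' Denatured states get a repulsive screened-Coulomb (MSA) structure
#' factor whose volume fraction scales with concentration; the
#' native-like state gets a weak attractive low-q enhancement instead
#' (its monomers attract near the isoelectric point).
#'
#' @param state a [sample_state_spec].
#' @param q momentum transfer grid (1/A).
#' @param concentrations mg/mL values (default the measured series
#'   3, 6, 15, 30).
#' @return List of [scattering_curve] objects, one per concentration.
#' @export
generate_sans <- function(state, q = seq(0.008, 0.25, by = 0.002),
                          concentrations = c(3, 6, 15, 30)) {
  .assert(inherits(state, "sample_state_spec"), "state must be a sample_state_spec")
  str <- state$structural
  P <- if (str$model == "guinier") {
    eval_generalized_guinier(q, 1, str$Rg, str$alpha)
  } else {
    eval_excluded_volume_form_factor(q, str$Rg, str$nu)
  }
  set.seed(state$seed)
  lapply(concentrations, function(cc) {
    if (str$model == "guinier") {
      ## weak low-q attraction, scaled with concentration
      S <- 1 + 0.25 * (cc / 30) * exp(-(q / 0.035)^2)
    } else {
      phi <- cc * 1e-3 * 0.72          # mg/mL x partial specific volume
      pars <- msa_params(sphere_radius = max(str$Rg / 2, 10),
                         volume_fraction = max(phi, 1e-6),
                         effective_charge = 8,
                         screening_length = 30,
                         temperature = state$temperature)
      S <- as.numeric(eval_msa_sq(q, pars, grid_points = 256))
    }
    ideal <- cc * P * S
    sig <- state$noise$sans_rel * pmax(abs(ideal), 1e-12)
    noisy <- if (state$noise$sans_rel > 0) ideal + stats::rnorm(length(q), 0, sig) else ideal
    scattering_curve(q, noisy, sig, concentration = cc,
                     temperature = state$temperature,
                     label = sprintf("%s synthetic SANS, %g mg/mL", state$name, cc))
  })
}

#' Generate synthetic NSE spectra for a folding state
#'
#' For the unfolded states the normalized ISF comes from the Zimm/ZIF
#' chain model with the state's published dynamical parameters; for the
#' native-like state it is a rigid-body decay
#' \eqn{\exp[-q^2 (D_0(q) + \Delta D(q)) t]} computed from a compact
#' coordinate fixture, where \eqn{\Delta D} is a single elastic-network
#' mode contribution scaled so internal dynamics supplies about 20% of
#' the total.  Seeded Gaussian noise grows linearly with Fourier time,
#' \eqn{\sigma(t) = \sigma_0 (1 + t/t_{max})}, emulating echo-amplitude
#' loss.
#'
#' @param state a [sample_state_spec].
#' @param q momentum transfers (1/A), default 0.05-0.15.
#' @param t Fourier-time grid (ns).
#' @return An [isf_set].
#' @export
generate_nse <- function(state, q = seq(0.03, 0.15, by = 0.01),
                         t = c(0, exp(seq(log(0.5), log(250), length.out = 40)))) {
  .assert(inherits(state, "sample_state_spec"), "state must be a sample_state_spec")
  tmax <- max(t)
  if (!is.na(state$dynamical$nu)) {
    spec <- .state_zimm_spec(state)
    isf <- simulate_spectra(spec, q, t, sample = paste0(state$name, " synthetic NSE"))
  } else {
    fx <- fixture_registry()
    sys <- rigid_body_system(fx$coordinates$compact20,
                             fx$diffusion_matrices$isotropic)
    ## scale the translational block to the state's DLS diffusion coefficient
    sys$D[1:3, 1:3] <- diag(3) * state$dynamical$D
    rb <- rigid_body_Dq(sys, q, n_orientations = 200)
    modes <- enm_modes(fx$coordinates$compact20, cutoff = 13)
    m7 <- mode_effective_diffusion(fx$coordinates$compact20,
                                   modes$eigenvectors[, 1],
                                   lambda_alpha = 1,
                                   k_alpha = modes$amplitudes[1],
                                   q = q, n_orientations = 200)
    ## scale the mode curve so internal motion is ~20% of the total
    target <- 0.25            # delta/D0 = 0.25 => delta/(D0+delta) = 0.2
    scale <- target * mean(rb$D0) / mean(m7$D_alpha)
    Dtot <- rb$D0 + scale * m7$D_alpha
    vals <- unlist(lapply(seq_along(q), function(i) exp(-q[i]^2 * Dtot[i] * t)))
    isf <- isf_set(q = rep(q, each = length(t)), t = rep(t, length(q)),
                   value = vals, sigma = rep(0, length(q) * length(t)),
                   sample = paste0(state$name, " synthetic NSE"),
                   temperature = state$temperature)
  }
  sig <- state$noise$isf_sigma0 * (1 + isf$t / tmax)
  set.seed(state$seed + 1L)
  noisy <- isf$value + if (state$noise$isf_sigma0 > 0)
    stats::rnorm(nrow(isf), 0, sig) else 0
  isf_set(isf$q, isf$t, noisy, sig,
          sample = attr(isf, "sample"), temperature = attr(isf, "temperature"))
}

#' Scalar side measurements for a folding state
#'
#' DLS diffusion coefficients, viscosities and the structure factor at
#' the DLS q value, as consumed by the hydrodynamic-function estimators.
#' Deterministic by default; with `perturb > 0` the values are jittered
#' by that relative amount under the state's seed (reproducibly).
#'
#' @param state a [sample_state_spec].
#' @param perturb relative Gaussian perturbation (default 0).
#' @return List with `S_q0`, `D_conc`, `D_0`, `eta_conc`, `eta_dilute`.
#' @export
generate_scalars <- function(state, perturb = 0) {
  .assert(inherits(state, "sample_state_spec"), "state must be a sample_state_spec")
  sc <- state$scalars
  if (perturb > 0) {
    set.seed(state$seed + 2L)
    sc <- lapply(sc, function(v)
      if (is.na(v)) v else v * (1 + stats::rnorm(1, 0, perturb)))
  }
  sc
}

#' Registry of coordinate and diffusion-matrix fixtures
#'
#' Self-contained toy systems for the rigid-body branch: a two-bead
#' dumbbell, a regular 4-bead tetrahedron, a 20-bead helical chain and a
#' 20-bead compact (globule-like) cluster, plus matching 6x6 diffusion
#' matrices (isotropic, and an axially anisotropic dumbbell matrix).
#' All coordinates are generated in code; no files are read.
#'
#' @return List with elements `coordinates` (named list of
#'   `scattering_centers`) and `diffusion_matrices` (named list of 6x6
#'   matrices).
#' @export
fixture_registry <- function() {
  bD <- neutron_scattering_lengths()[["D"]]
  dumbbell <- scattering_centers(rbind(c(-10, 0, 0), c(10, 0, 0)),
                                 b = c(bD, bD),
                                 label = c("bead1", "bead2"))
  tetra <- scattering_centers(7.5 * rbind(c(1, 1, 1), c(1, -1, -1),
                                          c(-1, 1, -1), c(-1, -1, 1)),
                              b = rep(bD, 4))
  ## helical 20-bead chain; tight pitch so 2nd/3rd neighbors fall inside
  ## the default elastic-network cutoff (keeps the network rigid)
  i <- 0:19
  helix <- cbind(5 * cos(i * 0.8), 5 * sin(i * 0.8), 2.8 * i)
  helix <- sweep(helix, 2, colMeans(helix))
  chain20 <- scattering_centers(helix, b = rep(bD, 20))
  ## compact cluster: deterministic low-discrepancy points in a 12 A sphere
  g <- (1 + sqrt(5)) / 2
  u <- ((i + 0.5) / 20)
  th <- acos(1 - 2 * u)
  ph <- 2 * pi * i / g
  rr <- 12 * u^(1 / 3)
  compact <- cbind(rr * sin(th) * cos(ph), rr * sin(th) * sin(ph),
                   rr * cos(th))
  compact <- sweep(compact, 2, colMeans(compact))
  compact20 <- scattering_centers(compact, b = rep(bD, 20))
  iso <- diag(c(rep(2.0, 3), rep(0.01, 3)))
  axial <- diag(c(2.4, 2.4, 3.0, 0.02, 0.02, 0.005))
  list(coordinates = list(dumbbell = dumbbell, tetrahedron = tetra,
                          chain20 = chain20, compact20 = compact20),
       diffusion_matrices = list(isotropic = iso, axial_dumbbell = axial))
}

#' Materialize synthetic fixtures to disk
#'
#' Writes, for each requested state, the SANS concentration series and
#' the NSE spectra in the package's text dialects, plus the fixture
#' diffusion matrices, into a directory -- everything the file-based
#' pipeline entry points consume.
#'
#' @param dir output directory (created if missing).
#' @param states character vector of state names.
#' @param seed integer seed.
#' @return Invisibly, the manifest of written files.
#' @export
materialize_fixtures <- function(dir, states = c("pd2", "gdmcl"), seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in states) {
    st <- sample_state_spec(nm, seed = seed)
    curves <- generate_sans(st)
    for (cur in curves) {
      f <- file.path(dir, sprintf("sans_%s_c%g.dat", nm, cur$concentration))
      write_sans_curve(cur, f)
      files <- c(files, f)
    }
    isf <- generate_nse(st)
    f <- file.path(dir, sprintf("nse_%s.dat", nm))
    write_isf(isf, f)
    files <- c(files, f)
  }
  fx <- fixture_registry()
  for (nm in names(fx$diffusion_matrices)) {
    f <- file.path(dir, sprintf("dmat_%s.dat", nm))
    .write_columns(as.data.frame(fx$diffusion_matrices[[nm]]), f,
                   header = "units = A^2/ns (tt), rad^2/ns (rr)")
    files <- c(files, f)
  }
  invisible(files)
}
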