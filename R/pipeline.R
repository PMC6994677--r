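#' Read a plain-text pipeline configuration
#'
#' Minimal sectioned key=value format: lines `[section]` open a section,
#' `key = value` lines populate it, `#` starts a comment.  Values are
#' parsed as numbers when possible, comma-separated lists become vectors.
#'
#' @param path file path.
#' @return Nested named list (sections of key-value pairs).
#' @export
read_config <- function(path) {
  .assert(file.exists(path), paste0("config not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    .assert(grepl("=", ln, fixed = TRUE),
            paste0("malformed config line: ", ln))
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    raw <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!anyNA(num)) num else parts
    if (length(val) == 0) val <- ""
    cfg[[section]][[key]] <- val
  }
  cfg
}

#' Write a pipeline configuration
#'
#' Inverse of [read_config]; round-trips losslessly for flat numeric /
#' string values and vectors.
#'
#' @param cfg nested named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (section in names(cfg)) {
    writeLines(paste0("[", section, "]"), con)
    for (key in names(cfg[[section]])) {
      val <- cfg[[section]][[key]]
      writeLines(paste0(key, " = ", paste(val, collapse = ", ")), con)
    }
  }
  invisible(path)
}

## run manifest: enough to reproduce deterministic stages bit-for-bit
.write_manifest <- function(out_dir, config, seed = NULL) {
  manifest <- list(
    package = "nsedyn",
    version = as.character(utils::packageVersion("nsedyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Structural analysis path: SANS to form/structure factor report
#'
#' Runs the structural branch of the pipeline: extrapolation of a
#' concentration series to infinite dilution, form-factor fit (Guinier or
#' excluded-volume chain), derived structural quantities (Flory exponent,
#' Kuhn length, end-to-end distance, compactness, overlap concentration),
#' and -- when a concentrated curve is supplied -- the experimental
#' structure factor with an optional MSA fit.
#'
#' @param curves list of [scattering_curve] objects (dilute series; a
#'   single curve skips extrapolation with a warning).
#' @param model `"guinier"` or `"excluded_volume"`.
#' @param R_H optional hydrodynamic radius (A) for the compactness report.
#' @param molar_mass optional molar mass (g/mol) for the overlap
#'   concentration.
#' @param concentrated optional [scattering_curve] of the concentrated
#'   solution; enables the structure-factor stage.
#' @param msa_init optional [msa_params] start values; enables the MSA fit.
#' @param N bead count for derived chain parameters.
#' @param out_dir optional output directory; when given, CSV/JSON reports
#'   and a manifest are written.
#' @return List of class `structural_report` with `form_factor_curve`,
#'   `fit`, `derived` (data.frame) and optionally `structure_factor`,
#'   `msa_fit`.
#' @export
run_structural <- function(curves, model = c("excluded_volume", "guinier"),
                           R_H = NULL, molar_mass = NULL,
                           concentrated = NULL, msa_init = NULL, N = 20,
                           out_dir = NULL) {
  model <- match.arg(model)
  if (inherits(curves, "scattering_curve")) curves <- list(curves)
  form <- if (length(curves) > 1) {
    extrapolate_infinite_dilution(curves)
  } else {
    warning("single dilute curve: extrapolation stage skipped")
    cur <- curves[[1]]
    cc <- if (cur$concentration > 0) cur$concentration else 1
    scattering_curve(cur$q, cur$intensity / cc, cur$sigma / cc,
                     concentration = 0, temperature = cur$temperature,
                     label = cur$label)
  }
  fit <- fit_form_factor(form, model, N = N)
  rg <- fit$radius_of_gyration
  derived <- data.frame(
    Rg = rg,
    nu = if (model == "excluded_volume") fit$flory_exponent else NA_real_,
    porod_m = if (model == "excluded_volume") fit$porod_exponent else NA_real_,
    kuhn_l = if (model == "excluded_volume") fit$kuhn_length else NA_real_,
    R_E = if (model == "excluded_volume") fit$end_to_end else NA_real_,
    R_H = if (!is.null(R_H)) R_H else NA_real_,
    compactness = if (!is.null(R_H)) compactness(R_H, rg)$ratio else NA_real_,
    c_star = if (!is.null(molar_mass))
      overlap_concentration(molar_mass, rg) else NA_real_)
  report <- list(form_factor_curve = form, fit = fit, derived = derived)
  if (!is.null(concentrated)) {
    report$structure_factor <- experimental_structure_factor(concentrated, form)
    if (!is.null(msa_init)) {
      report$msa_fit <- fit_msa(report$structure_factor, msa_init)
    }
  } else if (!is.null(msa_init)) {
    warning("no concentrated curve: structure-factor stage skipped")
  }
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    utils::write.csv(derived, file.path(out_dir, "structural_derived.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(form),
                     file.path(out_dir, "form_factor.csv"), row.names = FALSE)
    jsonlite::write_json(list(model = model, fit = unclass(fit)[
      setdiff(names(fit), "covariance")], derived = derived),
      file.path(out_dir, "structural_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    .write_manifest(out_dir, list(stage = "structural", model = model, N = N))
  }
  structure(report, class = c("structural_report", "list"))
}

#' Dynamical analysis path: NSE to cumulant / stretched / ZIF report
#'
#' Runs the dynamical branch: per-q initial-slope fits, effective
#' diffusion with the S(c,q)/H correction, stretched-exponential summary
#' (mean beta), Zimm-regime linearity diagnostic and the global ZIF fit
#' with free (D, tau_intern).
#'
#' @param isf an [isf_set].
#' @param spec a [zimm_model_spec] carrying the frozen chain parameters.
#' @param S_cq optional `structure_factor_curve`; if omitted, S = 1 with a
#'   prominent warning.
#' @param H_q0 hydrodynamic function (default 1; warned about when left
#'   at the default together with S).
#' @param out_dir optional output directory for CSV/JSON reports.
#' @return List of class `dynamical_report` with `cumulants`, `d_eff`,
#'   `linearity`, `stretched`, `mean_beta`, `zif` and a `zimm_consistent`
#'   flag (TRUE when the fitted internal friction is negligible).
#' @export
run_dynamical <- function(isf, spec, S_cq = NULL, H_q0 = 1, out_dir = NULL) {
  .assert(inherits(isf, "isf_set"), "isf must be an isf_set")
  cum <- fit_initial_slope(isf)
  if (is.null(S_cq) && H_q0 == 1) {
    warning("no structure factor / hydrodynamic function supplied: D_eff is uncorrected (S = H = 1)")
  }
  deff <- if (is.null(S_cq)) {
    suppressWarnings(effective_diffusion(cum, NULL, H_q0))
  } else {
    effective_diffusion(cum, S_cq, H_q0)
  }
  lin <- linearity_diagnostic(deff)
  stretched <- fit_stretched_exponential(isf)
  zif <- fit_zif_global(isf, spec)
  report <- list(cumulants = cum, d_eff = deff, linearity = lin,
                 stretched = stretched,
                 mean_beta = attr(stretched, "mean_beta"),
                 zif = zif,
                 zimm_consistent = zif$tau_intern < 0.5)
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    utils::write.csv(as.data.frame(cum)[, c("q", "A", "D1", "D1_se", "D2")],
                     file.path(out_dir, "cumulants.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(deff), file.path(out_dir, "d_eff.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mean_beta = report$mean_beta, linearity = lin,
           zif = list(D = zif$D, tau_intern = zif$tau_intern,
                      t_zimm = zif$t_zimm, chi2 = zif$chi2,
                      zimm_consistent = report$zimm_consistent)),
      file.path(out_dir, "dynamical_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(out_dir, list(stage = "dynamical",
                                  nu = spec$nu, l = spec$l, N = spec$N,
                                  eta = spec$eta, T = spec$temperature,
                                  H_q0 = H_q0))
  }
  structure(report, class = c("dynamical_report", "list"))
}

#' Rigid-body analysis path: coordinates to D0(q) and mode curves
#'
#' Computes the orientationally averaged form factor and first-cumulant
#' rigid-body diffusion coefficient curve from coordinates plus a 6x6
#' diffusion matrix, optionally the first elastic-network mode's
#' effective-diffusion curve, and -- when a measured curve is supplied --
#' the internal-dynamics decomposition.
#'
#' @param centers a `scattering_centers` object.
#' @param diffusion_matrix 6x6 matrix (or path to one, see
#'   [read_diffusion_matrix]).
#' @param q momentum transfer grid (1/A).
#' @param n_orientations quadrature directions.
#' @param enm run the elastic-network mode-7 branch (default TRUE when
#'   there are at least 4 centers).
#' @param lambda_alpha mode relaxation rate for the mode-7 curve (1/ns).
#' @param measured optional `effective_diffusion_curve` for the
#'   decomposition stage.
#' @param out_dir optional output directory.
#' @return List of class `rigidbody_report` with `form_factor`, `D0`,
#'   optionally `mode7` and `internal`.
#' @export
run_rigidbody <- function(centers, diffusion_matrix, q = seq(0.02, 0.3, by = 0.01),
                          n_orientations = 500, enm = nrow(centers) >= 4,
                          lambda_alpha = 1, measured = NULL, out_dir = NULL) {
  if (is.character(diffusion_matrix)) {
    diffusion_matrix <- read_diffusion_matrix(diffusion_matrix)
  }
  sys <- rigid_body_system(centers, diffusion_matrix)
  ff <- form_factor(centers, q)
  D0 <- rigid_body_Dq(sys, q, n_orientations)
  report <- list(form_factor = ff, D0 = D0)
  if (enm) {
    modes <- enm_modes(centers)
    report$modes <- modes
    report$mode7 <- mode_effective_diffusion(centers, modes$eigenvectors[, 1],
                                             lambda_alpha, modes$amplitudes[1],
                                             q, n_orientations)
  }
  if (!is.null(measured)) {
    report$internal <- internal_dynamics_residual(measured, D0)
  }
  if (!is.null(out_dir)) {
    .ensure_dir(out_dir)
    utils::write.csv(D0, file.path(out_dir, "rigid_body_D0.csv"),
                     row.names = FALSE)
    .write_columns(ff, file.path(out_dir, "form_factor_rigid.dat"),
                   header = "columns = q F")
    if (!is.null(report$internal)) {
      utils::write.csv(report$internal$curve,
                       file.path(out_dir, "delta_D_eff.csv"), row.names = FALSE)
    }
    .write_manifest(out_dir, list(stage = "rigidbody",
                                  n_orientations = n_orientations,
                                  lambda_alpha = lambda_alpha))
  }
  structure(report, class = c("rigidbody_report", "list"))
}
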