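#' One-dimensional SANS intensity profile
#'
#' Container for a single azimuthally averaged small-angle scattering curve
#' \eqn{I(q)} with 1-sigma uncertainties and sample metadata.  Momentum
#' transfer is stored internally in \eqn{\mathrm{\AA^{-1}}}; curves supplied
#' in \eqn{\mathrm{nm^{-1}}} are converted once at construction.
#'
#' @param q momentum transfer, strictly increasing, positive.
#' @param intensity scattered intensity (arbitrary units).
#' @param sigma 1-sigma uncertainty of `intensity` (same units); non-negative.
#' @param concentration protein concentration in mg/mL (0 = infinite dilution).
#' @param temperature sample temperature in K.
#' @param label free-text sample description.
#' @param q_unit `"1/A"` (default) or `"1/nm"`.
#'
#' @return Object of class `scattering_curve`: a list with fields `q`,
#'   `intensity`, `sigma`, `concentration`, `temperature`, `label`.
#' @examples
#' q <- seq(0.01, 0.3, by = 0.01)
#' sc <- scattering_curve(q, eval_generalized_guinier(q, 1, 15, 0),
#'                        sigma = rep(0.01, length(q)))
#' @export
scattering_curve <- function(q, intensity, sigma = rep(0, length(q)),
                             concentration = 0, temperature = 283.15,
                             label = "", q_unit = c("1/A", "1/nm")) {
  q_unit <- match.arg(q_unit)
  q <- as.numeric(q)
  if (q_unit == "1/nm") q <- q / 10
  .assert(length(q) > 0, "empty curve")
  .assert(all(is.finite(q)) && all(q > 0), "q must be positive and finite")
  .assert(all(diff(q) > 0), "q must be strictly increasing")
  .assert(length(intensity) == length(q) && length(sigma) == length(q),
          "intensity and sigma must have the same length as q")
  .assert(all(sigma >= 0), "sigma must be non-negative")
  structure(list(q = q, intensity = as.numeric(intensity),
                 sigma = as.numeric(sigma),
                 concentration = concentration,
                 temperature = temperature, label = label),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering_curve: %d points, q = [%.4g, %.4g] 1/A, c = %g mg/mL, T = %g K%s\n",
              length(x$q), min(x$q), max(x$q), x$concentration,
              x$temperature,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity, sigma = x$sigma)
}

#' Read a SANS curve from a 3-column text file
#'
#' Plain-text dialect: optional `# key = value` header lines carrying
#' `concentration` (mg/mL), `temperature` (K), `label` and `q_unit`
#' (`1/A` or `1/nm`), followed by whitespace-separated columns
#' `q  I  sigma` (sigma optional; missing sigma is filled with zero).
#'
#' @param path file path.
#' @return A [scattering_curve].
#' @export
read_sans_curve <- function(path) {
  parsed <- .read_commented_table(path)
  .assert(length(parsed$body) > 0, paste0("no data rows in ", path))
  fields <- lapply(parsed$body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  ncols <- vapply(fields, length, integer(1))
  .assert(all(ncols >= 2), "SANS rows need at least 2 columns (q, I)")
  num <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(num, function(v) any(is.na(v)), logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed rows in %s at line(s): %s", path,
                 paste(parsed$body_index[bad], collapse = ", ")), call. = FALSE)
  }
  q <- vapply(num, `[`, numeric(1), 1)
  i <- vapply(num, `[`, numeric(1), 2)
  s <- vapply(num, function(v) if (length(v) >= 3) v[3] else 0, numeric(1))
  h <- parsed$headers
  scattering_curve(q, i, s,
                   concentration = if (!is.null(h$concentration)) h$concentration else 0,
                   temperature = if (!is.null(h$temperature)) h$temperature else 283.15,
                   label = if (!is.null(h$label)) as.character(h$label) else "",
                   q_unit = if (!is.null(h$q_unit) && h$q_unit == "1/nm") "1/nm" else "1/A")
}

#' Write a SANS curve in the 3-column text dialect
#'
#' @param curve a [scattering_curve].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sans_curve <- function(curve, path) {
  .assert(inherits(curve, "scattering_curve"), "not a scattering_curve")
  .write_columns(as.data.frame(curve), path,
                 header = c(paste("concentration =", curve$concentration),
                            paste("temperature =", curve$temperature),
                            paste("label =", curve$label),
                            "q_unit = 1/A"))
}
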