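#' Set of normalized intermediate scattering functions
#'
#' Container for NSE data: normalized ISF values \eqn{S(q,t)/S(q,0)} on a
#' (q, Fourier-time) grid, stored in long format with one row per (q, t)
#' point plus 1-sigma uncertainties and sample metadata.
#'
#' @param q momentum transfer per row (1/A).
#' @param t Fourier time per row (ns), non-negative, ascending within each q.
#' @param value normalized ISF.
#' @param sigma 1-sigma uncertainty (>= 0).
#' @param sample sample description string.
#' @param temperature temperature in K.
#' @return Object of class `isf_set`: a `data.frame` with columns
#'   `q`, `t`, `value`, `sigma` and attributes `sample`, `temperature`.
#' @examples
#' isf <- isf_set(q = rep(0.1, 3), t = c(0, 5, 10),
#'                value = exp(-0.02 * c(0, 5, 10)), sigma = rep(0.01, 3))
#' @export
isf_set <- function(q, t, value, sigma = rep(0, length(q)),
                    sample = "", temperature = 283.15) {
  n <- length(q)
  .assert(length(t) == n && length(value) == n && length(sigma) == n,
          "q, t, value, sigma must have equal length")
  .assert(all(t >= 0), "Fourier times must be non-negative")
  .assert(all(sigma >= 0), "sigma must be non-negative")
  df <- data.frame(q = as.numeric(q), t = as.numeric(t),
                   value = as.numeric(value), sigma = as.numeric(sigma))
  df <- df[order(df$q, df$t), , drop = FALSE]
  rownames(df) <- NULL
  for (qq in unique(df$q)) {
    sub <- df[df$q == qq, ]
    .assert(!anyDuplicated(sub$t),
            sprintf("duplicated Fourier times at q = %g", qq))
    v1 <- sub$value[1]; s1 <- max(sub$sigma[1], 1e-12)
    .assert(v1 <= 1.05 + 3 * s1,
            sprintf("ISF at the smallest time exceeds 1.05 beyond 3 sigma at q = %g", qq))
  }
  structure(df, class = c("isf_set", "data.frame"),
            sample = sample, temperature = temperature)
}

#' @export
print.isf_set <- function(x, ...) {
  qs <- unique(x$q)
  cat(sprintf("isf_set: %d q values (%.3g-%.3g 1/A), %d points, t = [%.3g, %.3g] ns, sample '%s'\n",
              length(qs), min(qs), max(qs), nrow(x),
              min(x$t), max(x$t), attr(x, "sample")))
  invisible(x)
}

#' Read NSE intermediate scattering functions from text
#'
#' Two dialects are accepted.  Block dialect: `# key = value` headers
#' (`sample`, `temperature`, `t_unit` of `ns` or `us`), then per-q blocks
#' starting with a line `q = <value>` followed by rows `t  S/S0  sigma`.
#' Flat dialect: 4 columns `q  t  S/S0  sigma` throughout.  A missing
#' sigma column is filled with a constant 2% relative error (with a
#' warning); times declared in microseconds are converted to ns.
#'
#' @param path file path.
#' @return An [isf_set].
#' @export
read_isf <- function(path) {
  parsed <- .read_commented_table(path)
  .assert(length(parsed$body) > 0, paste0("no data rows in ", path))
  h <- parsed$headers
  t_scale <- 1
  if (!is.null(h$t_unit)) {
    .assert(h$t_unit %in% c("ns", "us"), "t_unit must be 'ns' or 'us'")
    if (h$t_unit == "us") t_scale <- 1e3
  }
  body <- parsed$body
  qlines <- grepl("^\\s*q\\s*=", body)
  rows <- list()
  warn_sigma <- FALSE
  if (any(qlines)) {
    cur_q <- NA_real_
    for (i in seq_along(body)) {
      ln <- body[i]
      if (qlines[i]) {
        cur_q <- as.numeric(sub("^\\s*q\\s*=\\s*", "", ln))
        .assert(is.finite(cur_q), sprintf("malformed q line %d", parsed$body_index[i]))
        next
      }
      .assert(is.finite(cur_q), "data row before any 'q =' line")
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (any(is.na(v)) || length(v) < 2) {
        stop(sprintf("malformed row in %s at line %d", path, parsed$body_index[i]),
             call. = FALSE)
      }
      if (length(v) < 3) { v <- c(v, NA); warn_sigma <- TRUE }
      rows[[length(rows) + 1]] <- c(cur_q, v[1], v[2], v[3])
    }
  } else {
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
      if (any(is.na(v[1:3])) || length(v) < 3) {
        stop(sprintf("malformed row in %s at line %d", path, parsed$body_index[i]),
             call. = FALSE)
      }
      if (length(v) < 4) { v <- c(v, NA); warn_sigma <- TRUE }
      rows[[length(rows) + 1]] <- v[1:4]
    }
  }
  m <- do.call(rbind, rows)
  sigma <- m[, 4]
  if (warn_sigma || anyNA(sigma)) {
    warning("no sigma column: filled with a constant 2% relative error")
    sigma[is.na(sigma)] <- 0.02 * abs(m[is.na(sigma), 3])
  }
  ## per-q monotonicity check before construction
  for (qq in unique(m[, 1])) {
    tt <- m[m[, 1] == qq, 2]
    .assert(all(diff(tt) > 0),
            sprintf("Fourier times not strictly increasing at q = %g", qq))
  }
  isf_set(q = m[, 1], t = m[, 2] * t_scale, value = m[, 3], sigma = sigma,
          sample = if (!is.null(h$sample)) as.character(h$sample) else "",
          temperature = if (!is.null(h$temperature)) h$temperature else 283.15)
}

#' Write an ISF set in the block text dialect
#'
#' @param isf an [isf_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isf <- function(isf, path) {
  .assert(inherits(isf, "isf_set"), "not an isf_set")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# sample = ", attr(isf, "sample")),
               paste0("# temperature = ", attr(isf, "temperature")),
               "# t_unit = ns"), con)
  for (qq in unique(isf$q)) {
    writeLines(sprintf("q = %.6g", qq), con)
    sub <- isf[isf$q == qq, ]
    utils::write.table(sub[, c("t", "value", "sigma")], con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
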