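## internal helpers shared across modules

.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

## linear interpolation in (q, I); extrapolation forbidden
.interp_curve <- function(x, y, xout) {
  .assert(all(xout >= min(x) - 1e-12) && all(xout <= max(x) + 1e-12),
          "interpolation requested outside the common q range")
  stats::approx(x, y, xout = xout, rule = 1)$y
}

## replace zero/non-finite uncertainties by the median positive one
.clean_sigma <- function(sigma, context = "curve") {
  bad <- !is.finite(sigma) | sigma <= 0
  if (all(bad)) return(rep(1, length(sigma)))
  if (any(bad)) sigma[bad] <- stats::median(sigma[!bad])
  sigma
}

## centered moving average keeping edges (partial windows)
.moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- floor(window / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    mean(x[idx])
  }, numeric(1))
}

## effective number of points averaged at each position (for sigma propagation)
.moving_average_n <- function(n, window) {
  if (window <= 1) return(rep(1, n))
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    length(max(1, i - half):min(n, i + half))
  }, numeric(1))
}

## parameter covariance from a converged nls.lm fit; NULL if singular
.nlslm_cov <- function(fit, npar) {
  h <- fit$hessian
  cov <- tryCatch(solve(0.5 * h), error = function(e) NULL)
  if (is.null(cov)) return(matrix(NA_real_, npar, npar))
  cov
}

.is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

## write a data.frame as a plain 3+-column text file with '#' header lines
.write_columns <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## parse '# key = value' headers from a text file; returns list(headers, lines)
.read_commented_table <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  is_com <- grepl("^\\s*#", lines)
  headers <- list()
  for (h in sub("^\\s*#\\s*", "", lines[is_com])) {
    if (grepl("=", h, fixed = TRUE)) {
      kv <- strsplit(h, "=", fixed = TRUE)[[1]]
      key <- tolower(trimws(kv[1]))
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      headers[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_com & nzchar(trimws(lines))]
  list(headers = headers, body = body, body_index = which(!is_com & nzchar(trimws(lines))))
}
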