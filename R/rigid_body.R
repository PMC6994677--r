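#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths of the elements that occur in
#' proteins and common cofactors, in fm (standard tabulated values).
#' `"D"` is deuterium.
#'
#' @return Named numeric vector, fm.
#' @export
neutron_scattering_lengths <- function() {
  c(H = -3.7390, D = 6.671, C = 6.6460, N = 9.36, O = 5.803,
    S = 2.847, P = 5.13, FE = 9.45, ZN = 5.680, SE = 7.970,
    NA. = 3.63, MG = 5.375, CL = 9.5770, K = 3.67, CA = 4.70,
    CU = 7.718, MN = -3.73, I = 5.28, F = 5.654, BR = 6.795)
}

.element_b <- function(elements) {
  tab <- neutron_scattering_lengths()
  key <- toupper(trimws(elements))
  key[key == "NA"] <- "NA."
  b <- tab[key]
  if (anyNA(b)) {
    bad <- which(is.na(b))
    stop("unknown element(s) in coordinate records: ",
         paste(sprintf("atom %d ('%s')", bad, elements[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(b)
}

#' Read scattering centers from a PDB file
#'
#' Parses a standard PDB file (via the bio3d reader; first-listed altLoc
#' kept, HETATM skipped unless requested) and attaches a coherent neutron
#' scattering length to every atom.  With `deuterate_labile = TRUE`, the
#' labile hydrogens -- those whose nearest heavy atom within 1.3 A is N,
#' O or S -- take the deuterium scattering length, emulating H/D exchange
#' of the surface and backbone protons in heavy-water buffers.  With
#' `coarse_grain = TRUE` atoms are aggregated per residue: total b at the
#' b-weighted centroid.
#'
#' @param path PDB file path.
#' @param deuterate_labile replace labile-H scattering lengths by
#'   deuterium's (default FALSE).
#' @param coarse_grain one bead per residue (default FALSE).
#' @param include_het include HETATM records (default FALSE).
#' @return Object of class `scattering_centers`: `data.frame` with columns
#'   `x`, `y`, `z` (A), `b` (fm), `label`.
#' @export
read_coordinates <- function(path, deuterate_labile = FALSE,
                             coarse_grain = FALSE, include_het = FALSE) {
  .assert(file.exists(path), paste0("file not found: ", path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("PDB parse failed: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  ## altLoc: keep blank or first occurring per (residue, atom name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    at <- at[!duplicated(key), , drop = FALSE]
  }
  .assert(nrow(at) > 0, "no atoms found in PDB file")
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele)) || all(!nzchar(trimws(ele)))) {
    ele <- substr(trimws(at$elety), 1, 1)
  }
  ele <- trimws(ele)
  miss <- is.na(ele) | !nzchar(ele)
  ele[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  b <- .element_b(ele)
  xyz <- cbind(at$x, at$y, at$z)
  if (deuterate_labile) {
    is_h <- toupper(ele) == "H"
    heavy <- which(!is_h)
    bD <- neutron_scattering_lengths()[["D"]]
    for (i in which(is_h)) {
      d2 <- (xyz[heavy, 1] - xyz[i, 1])^2 + (xyz[heavy, 2] - xyz[i, 2])^2 +
        (xyz[heavy, 3] - xyz[i, 3])^2
      j <- heavy[which.min(d2)]
      if (length(j) && d2[which.min(d2)] <= 1.3^2 &&
          toupper(ele[j]) %in% c("N", "O", "S")) {
        b[i] <- bD
      }
    }
  }
  label <- paste0(at$resid, at$resno, ":", trimws(at$elety))
  centers <- data.frame(x = at$x, y = at$y, z = at$z, b = b, label = label,
                        stringsAsFactors = FALSE)
  if (coarse_grain) {
    rkey <- paste(at$chain, at$resno)
    agg <- lapply(split(seq_len(nrow(centers)), rkey), function(idx) {
      bi <- centers$b[idx]
      bw <- sum(bi)
      .assert(abs(bw) > 1e-9, "residue with zero total scattering length")
      data.frame(x = sum(bi * centers$x[idx]) / bw,
                 y = sum(bi * centers$y[idx]) / bw,
                 z = sum(bi * centers$z[idx]) / bw,
                 b = bw,
                 label = paste0(at$resid[idx[1]], at$resno[idx[1]]),
                 stringsAsFactors = FALSE)
    })
    centers <- do.call(rbind, agg)
    ## keep chain order
    centers <- centers[order(match(rownames(centers), unique(rkey))), ]
    rownames(centers) <- NULL
  }
  structure(centers, class = c("scattering_centers", "data.frame"))
}

#' Build scattering centers from raw coordinates
#'
#' @param xyz n x 3 matrix of positions (A).
#' @param b coherent scattering lengths (fm), length n.
#' @param label optional labels.
#' @return A `scattering_centers` data.frame.
#' @export
scattering_centers <- function(xyz, b, label = NULL) {
  xyz <- as.matrix(xyz)
  .assert(ncol(xyz) == 3 && nrow(xyz) >= 1, "xyz must be an n x 3 matrix")
  .assert(all(is.finite(xyz)), "positions must be finite")
  .assert(length(b) == nrow(xyz), "b must match the number of centers")
  if (is.null(label)) label <- paste0("c", seq_len(nrow(xyz)))
  structure(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       b = as.numeric(b), label = label,
                       stringsAsFactors = FALSE),
            class = c("scattering_centers", "data.frame"))
}

#' Rigid-body system: scattering centers plus diffusion matrix
#'
#' Couples a set of scattering centers with the 6x6 generalized diffusion
#' matrix (translational block in A^2/ns, rotational block in rad^2/ns,
#' mixed coupling blocks) expressed about the center of diffusion.
#'
#' @param centers a `scattering_centers` object.
#' @param diffusion_matrix symmetric positive semidefinite 6x6 matrix.
#' @return Object of class `rigid_body_system`.
#' @export
rigid_body_system <- function(centers, diffusion_matrix) {
  .assert(inherits(centers, "scattering_centers"),
          "centers must be scattering_centers")
  D <- as.matrix(diffusion_matrix)
  .assert(all(dim(D) == c(6, 6)), "diffusion matrix must be 6x6")
  .assert(max(abs(D - t(D))) < 1e-8 * max(abs(D), 1),
          "diffusion matrix must be symmetric")
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  .assert(min(ev) > -1e-8 * max(abs(ev), 1),
          "diffusion matrix must be positive semidefinite")
  structure(list(centers = centers, D = (D + t(D)) / 2),
            class = "rigid_body_system")
}

#' Read a 6x6 diffusion matrix from whitespace-separated text
#'
#' Expects 6 rows of 6 numbers; `#` comment lines may carry a units
#' header (`units = A^2/ns, rad^2/ns`).
#'
#' @param path file path.
#' @return 6x6 numeric matrix.
#' @export
read_diffusion_matrix <- function(path) {
  parsed <- .read_commented_table(path)
  .assert(length(parsed$body) == 6, "diffusion matrix file must have 6 rows")
  m <- do.call(rbind, lapply(parsed$body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  .assert(!anyNA(m) && ncol(m) == 6, "malformed diffusion matrix")
  m
}

#' Deterministic spherical quadrature directions
#'
#' Fibonacci-lattice point set on the unit sphere: near-uniform,
#' deterministic and therefore reproducible orientation averaging.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  .assert(n >= 1, "n must be >= 1")
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Orientationally averaged form factor of a rigid body
#'
#' \eqn{F(q) = \langle |\sum_j b_j e^{i q \cdot r_j}|^2\rangle}, evaluated
#' with the exact Debye double sum
#' \eqn{F(q) = \sum_{jk} b_j b_k \, \mathrm{sinc}(q r_{jk})}.
#'
#' @param centers a `scattering_centers` object.
#' @param q momentum transfer grid (1/A).
#' @return Object of class `form_factor_table`: `data.frame` with `q` and
#'   `F` (fm^2); `F(0) = (\sum b)^2`.
#' @export
form_factor <- function(centers, q) {
  .assert(inherits(centers, "scattering_centers"),
          "centers must be scattering_centers")
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  b <- centers$b
  dmat <- as.matrix(stats::dist(xyz))
  Fq <- vapply(q, function(qq) {
    x <- qq * dmat
    sk <- ifelse(x < 1e-10, 1, sin(x) / x)
    sum(outer(b, b) * sk)
  }, numeric(1))
  structure(data.frame(q = q, F = Fq),
            class = c("form_factor_table", "data.frame"))
}

## complex amplitude sums over a direction set; returns list of matrices
## phase[j, dir] = exp(i q r_j . u_dir)
.phase_matrix <- function(xyz, b, qvecs) {
  arg <- xyz %*% t(qvecs)              # n_centers x n_dir
  exp(1i * arg)
}

#' Rigid-body first-cumulant diffusion coefficient
#'
#' Effective diffusion coefficient of a rigid scatterer with coupled
#' translational-rotational Brownian motion:
#' \deqn{D_0(q) = \frac{1}{q^2 F(q)} \left\langle
#'   \left(\sum_j b_j e^{i q\cdot r_j}
#'   \begin{pmatrix} q \\ q \times r_j\end{pmatrix}\right)^{\!\dagger}
#'   \mathbf{D}
#'   \left(\sum_k b_k e^{i q\cdot r_k}
#'   \begin{pmatrix} q \\ q \times r_k \end{pmatrix}\right)
#'   \right\rangle}
#' with conjugate phases on the two indices (which makes the average real
#' and reduces to \eqn{D_0 = D} for isotropic translation) and the
#' orientational average evaluated by a deterministic spherical
#' quadrature.  The form factor in the denominator uses the same
#' quadrature, so analytic limits hold exactly point-set by point-set.
#'
#' A convergence check doubles the number of directions; a relative
#' change above 1% triggers a warning, and both values are returned in
#' the `convergence` attribute.
#'
#' @param system a [rigid_body_system].
#' @param q momentum transfer grid (1/A), positive.
#' @param n_orientations quadrature directions (default 500).
#' @return `data.frame` with `q` and `D0` (A^2/ns); attribute
#'   `convergence` holds the doubled-quadrature values.
#' @export
rigid_body_Dq <- function(system, q, n_orientations = 500) {
  .assert(inherits(system, "rigid_body_system"),
          "system must be a rigid_body_system")
  .assert(all(q > 0), "q must be positive")
  eval_at <- function(ndir) {
    u <- fibonacci_sphere(ndir)
    xyz <- as.matrix(system$centers[, c("x", "y", "z")])
    b <- system$centers$b
    D <- system$D
    vapply(q, function(qq) {
      qv <- qq * u                      # ndir x 3
      ph <- .phase_matrix(xyz, b, qv)   # n x ndir
      num <- 0; den <- 0
      for (d in seq_len(ndir)) {
        qd <- qv[d, ]
        cross <- cbind(qd[2] * xyz[, 3] - qd[3] * xyz[, 2],
                       qd[3] * xyz[, 1] - qd[1] * xyz[, 3],
                       qd[1] * xyz[, 2] - qd[2] * xyz[, 1])
        amp <- b * ph[, d]
        w <- c(colSums(amp * matrix(qd, nrow(xyz), 3, byrow = TRUE)),
               colSums(amp * cross))
        num <- num + Re(Conj(w) %*% D %*% w)
        den <- den + abs(sum(amp))^2
      }
      num / (qq^2 * den)
    }, numeric(1))
  }
  D0 <- eval_at(n_orientations)
  D0_check <- eval_at(2 * n_orientations)
  rel <- abs(D0_check - D0) / pmax(abs(D0), 1e-12)
  if (any(rel > 0.01)) {
    warning(sprintf("orientation quadrature not converged at %d points (max rel. change %.2g)",
                    n_orientations, max(rel)))
  }
  out <- data.frame(q = q, D0 = D0)
  attr(out, "convergence") <- data.frame(q = q, D0_doubled = D0_check,
                                         rel_change = rel)
  out
}

#' Internal-dynamics residual of measured effective diffusion
#'
#' Pointwise difference \eqn{\Delta D_{eff}(q) = D_{eff}(q) - D_0(q)}
#' between the measured (interaction-corrected) NSE diffusion
#' coefficients and the calculated rigid-body translation-rotation
#' contribution, with the rigid curve interpolated onto the measured q
#' grid.  Also reports the average fractional contribution
#' \eqn{\langle \Delta D / D_{eff} \rangle} of internal dynamics.
#'
#' @param measured an `effective_diffusion_curve`.
#' @param rigid `data.frame` with `q` and `D0` (from [rigid_body_Dq]).
#' @return List with `curve` (data.frame `q`, `delta_D`, `sigma`) and
#'   `fractional_contribution`.
#' @export
internal_dynamics_residual <- function(measured, rigid) {
  .assert(inherits(measured, "effective_diffusion_curve"),
          "measured must be an effective_diffusion_curve")
  .assert(all(c("q", "D0") %in% names(rigid)), "rigid needs columns q, D0")
  qlo <- max(min(measured$q), min(rigid$q))
  qhi <- min(max(measured$q), max(rigid$q))
  sel <- measured$q >= qlo & measured$q <= qhi
  .assert(any(sel), "no overlapping q support")
  q <- measured$q[sel]
  d0 <- .interp_curve(rigid$q, rigid$D0, q)
  dd <- measured$D_eff[sel] - d0
  list(curve = data.frame(q = q, delta_D = dd, sigma = measured$sigma[sel]),
       fractional_contribution = mean(dd / measured$D_eff[sel]))
}
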