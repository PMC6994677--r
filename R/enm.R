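#' Elastic-network normal modes
#'
#' Anisotropic elastic-network model: every pair of centers closer than
#' `cutoff` is connected by a Hookean spring of uniform stiffness, the
#' 3n x 3n Hessian is mass-weighted with a uniform mean mass and
#' diagonalized.  A connected network has exactly six near-zero
#' (rigid-body) eigenvalues; internal modes are numbered from alpha = 7
#' upward.  Mode amplitudes follow equipartition,
#' \eqn{k_\alpha = k_B T / (\bar m \omega_\alpha^2)}.
#'
#' Units: with the spring constant expressed in \eqn{k_B T / \mathrm{A^2}}
#' the amplitudes \eqn{k_\alpha} come out directly in \eqn{\mathrm{A^2}};
#' mode relaxation rates are not predicted by the harmonic model and are
#' supplied externally where needed (see [mode_effective_diffusion]).
#'
#' @param centers a `scattering_centers` object (n >= 2).
#' @param cutoff spring cutoff distance (A), default 13.
#' @param spring_constant uniform stiffness in \eqn{k_B T / \mathrm{A^2}},
#'   default 1.
#' @param mean_mass average bead mass in amu (recorded; default 110, one
#'   residue).
#' @return Object of class `normal_mode_set`: list with `eigenvectors`
#'   (3n x n_modes, orthonormal, internal modes only), `eigenvalues`
#'   (omega^2 in spring-constant/mass units), `amplitudes` (k_alpha, A^2),
#'   `mode_numbers` (7, 8, ...), `mean_mass`, `n_centers`, `cutoff`.
#' @export
enm_modes <- function(centers, cutoff = 13, spring_constant = 1,
                      mean_mass = 110) {
  .assert(inherits(centers, "scattering_centers"),
          "centers must be scattering_centers")
  n <- nrow(centers)
  .assert(n >= 2, "need at least 2 centers")
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  adj <- dm > 0 & dm <= cutoff
  ## connectivity check (breadth-first)
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(seen)) {
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A; increase the cutoff", call. = FALSE)
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in which(adj[i, ] & seq_len(n) > i)) {
      dv <- xyz[j, ] - xyz[i, ]
      d2 <- sum(dv^2)
      blk <- -spring_constant * tcrossprod(dv) / d2
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)               # ascending
  vecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  nzero <- sum(vals < 1e-8 * max(vals))
  ## 6 rigid-body modes in general; 5 for a strict two-body system
  expected_zero <- if (n == 2) 5L else 6L
  if (nzero != expected_zero) {
    stop(sprintf("expected %d rigid-body modes, found %d near-zero eigenvalues (degenerate or disconnected geometry)",
                 expected_zero, nzero), call. = FALSE)
  }
  first_internal <- nzero + 1L
  keep <- first_internal:(3 * n)
  structure(list(eigenvectors = vecs[, keep, drop = FALSE],
                 eigenvalues = vals[keep],
                 amplitudes = 1 / vals[keep],   # kB T / (m omega^2) in A^2
                 mode_numbers = seq_along(keep) + nzero,
                 mean_mass = mean_mass,
                 n_centers = n,
                 cutoff = cutoff,
                 spring_constant = spring_constant),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("normal_mode_set: %d centers, %d internal modes (first eigenvalue %.4g), cutoff %.1f A\n",
              x$n_centers, length(x$eigenvalues), x$eigenvalues[1], x$cutoff))
  invisible(x)
}

#' Mode-specific effective diffusion coefficient
#'
#' Contribution of one internal normal mode to the q-dependent effective
#' diffusion coefficient:
#' \deqn{D_{eff}^{\alpha}(q) = \frac{\lambda_\alpha k_\alpha}{q^2 F(q)}
#'   \left\langle \Big| \sum_j b_j e^{i q \cdot r_j}
#'   (q \cdot e_j^{\alpha}) \Big|^2 \right\rangle}
#' (a symmetric double sum over center pairs), evaluated with the same
#' deterministic spherical quadrature as [rigid_body_Dq]; the denominator
#' uses the quadrature-averaged form factor.  Non-negative by
#' construction and invariant under a global sign flip of the
#' eigenvector.
#'
#' @param centers a `scattering_centers` object.
#' @param eigenvector mode displacement vector, length 3n (x1, y1, z1,
#'   x2, ...).
#' @param lambda_alpha mode relaxation rate (1/ns).  The harmonic network
#'   does not predict it; results scale linearly with this input.
#' @param k_alpha mode amplitude (A^2).
#' @param q momentum transfer grid (1/A), positive.
#' @param n_orientations quadrature directions (default 500).
#' @return `data.frame` with `q` and `D_alpha` (A^2/ns).
#' @export
mode_effective_diffusion <- function(centers, eigenvector, lambda_alpha,
                                     k_alpha, q, n_orientations = 500) {
  .assert(inherits(centers, "scattering_centers"),
          "centers must be scattering_centers")
  n <- nrow(centers)
  .assert(length(eigenvector) == 3 * n,
          "eigenvector length must be 3 x number of centers")
  .assert(all(q > 0), "q must be positive")
  .assert(k_alpha >= 0, "k_alpha must be >= 0")
  xyz <- as.matrix(centers[, c("x", "y", "z")])
  b <- centers$b
  evec <- matrix(eigenvector, ncol = 3, byrow = TRUE)   # n x 3
  u <- fibonacci_sphere(n_orientations)
  Dq <- vapply(q, function(qq) {
    qv <- qq * u
    ph <- .phase_matrix(xyz, b, qv)                     # n x ndir
    proj <- evec %*% t(u) * qq                          # n x ndir, q . e_j
    amp <- colSums(b * ph * proj)                       # per direction
    den <- colSums(b * ph)
    num <- mean(abs(amp)^2)
    Fq <- mean(abs(den)^2)
    lambda_alpha * k_alpha * num / (qq^2 * Fq)
  }, numeric(1))
  data.frame(q = q, D_alpha = Dq)
}
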