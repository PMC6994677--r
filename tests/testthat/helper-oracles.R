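## Independent oracles used across the suite.  These deliberately share no
## code with the package: plain loops, closed forms, Monte-Carlo averages.

## Percus-Yevick hard-sphere structure factor, closed form via the
## analytic direct correlation function.
py_hard_sphere_sq <- function(q, eta) {
  a <- (1 + 2 * eta)^2 / (1 - eta)^4
  b <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  d <- eta * a / 2
  s <- sin(q); ct <- cos(q)
  I1 <- (s - q * ct) / q^3
  I2 <- (2 * q * s - (q^2 - 2) * ct - 2) / q^4
  I3 <- ((4 * q^3 - 24 * q) * s - (q^4 - 12 * q^2 + 24) * ct + 24) / q^6
  chat <- -4 * pi * (a * I1 + b * I2 + d * I3)
  rho <- 6 * eta / pi
  1 / (1 - rho * chat)
}

## Debye function (Gaussian-chain form factor), closed form.
debye_fn <- function(x) ifelse(x < 1e-10, 1, 2 * (exp(-x) + x - 1) / x^2)

## Brute-force bead-pair correlator: plain triple loop over modes.
brute_B <- function(n, m, t, N, nu, l, RE, tau, A = rep(1, length(tau))) {
  val <- abs(n - m)^(2 * nu) * l^2
  for (p in seq_along(tau)) {
    val <- val + (4 * RE^2 / pi^2) * A[p] / p^(2 * nu + 1) *
      cos(pi * p * n / N) * cos(pi * p * m / N) * (1 - exp(-t / tau[p]))
  }
  val
}

## Brute-force chain ISF: independent double loop over bead pairs.
brute_zimm_isf <- function(q, tvec, N, nu, l, RE, tau, D, HS = 1,
                           A = rep(1, length(tau))) {
  one_t <- function(tt) {
    acc <- 0
    for (n in 0:(N - 1)) for (m in 0:(N - 1)) {
      acc <- acc + exp(-q^2 * brute_B(n, m, tt, N, nu, l, RE, tau, A) / 6)
    }
    exp(-q^2 * D * HS * tt) * acc / N
  }
  i0 <- one_t(0)
  vapply(tvec, function(tt) one_t(tt) / i0, numeric(1))
}

## Monte-Carlo orientation average of the rigid-body first cumulant
## (independent implementation of the bilinear form, random directions;
## vectorized over directions for speed but sharing no package code).
mc_rigid_Dq <- function(xyz, b, Dmat, q, n_mc = 1e5, seed = 99) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_mc), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(xyz)
  vapply(q, function(qq) {
    qv <- qq * u                                    # n_mc x 3
    ph <- exp(1i * (qv %*% t(xyz)))                 # n_mc x n
    ## w components: 6 x n_mc accumulated over centers
    w <- matrix(0 + 0i, n_mc, 6)
    for (j in seq_len(n)) {
      cr <- cbind(qv[, 2] * xyz[j, 3] - qv[, 3] * xyz[j, 2],
                  qv[, 3] * xyz[j, 1] - qv[, 1] * xyz[j, 3],
                  qv[, 1] * xyz[j, 2] - qv[, 2] * xyz[j, 1])
      w <- w + b[j] * ph[, j] * cbind(qv, cr)
    }
    num <- Re(rowSums((Conj(w) %*% Dmat) * w))
    den <- Mod(ph %*% b)^2
    sum(num) / (qq^2 * sum(den))
  }, numeric(1))
}

## Monte-Carlo orientation average of the mode-specific diffusion sum.
mc_mode_Dq <- function(xyz, b, evec3, lambda, kamp, q, n_mc = 1e5, seed = 99) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_mc), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  vapply(q, function(qq) {
    qv <- qq * u
    ph <- exp(1i * (qv %*% t(xyz)))                 # n_mc x n
    proj <- qv %*% t(evec3)                         # n_mc x n
    amp <- rowSums(ph * proj * rep(b, each = n_mc))
    tot <- ph %*% b
    lambda * kamp * sum(Mod(amp)^2) / (qq^2 * sum(Mod(tot)^2))
  }, numeric(1))
}

## Write a tiny PDB file; atoms = data.frame(name, resn, resno, x, y, z, ele)
write_mini_pdb <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, a$name, " ", a$resn, "A", a$resno, a$x, a$y, a$z, 1.0, 0.0,
            a$ele)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

## default deterministic test seed used throughout the suite
TEST_SEED <- 1L
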