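test_that("PDB reading assigns elements and scattering lengths", {
  atoms <- data.frame(
    name = c("N", "CA", "O"), resn = "GLY", resno = 1,
    x = c(0, 1.5, 2.9), y = 0, z = 0, ele = c("N", "C", "O"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(atoms, path)
  ctr <- read_coordinates(path)
  expect_equal(nrow(ctr), 3)
  b <- neutron_scattering_lengths()
  expect_equal(ctr$b, unname(b[c("N", "C", "O")]))
  ## empty file is rejected
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_coordinates(empty))
  ## unknown element is reported with its record
  bad <- atoms; bad$ele[2] <- "XX"
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(bad, path2)
  expect_error(read_coordinates(path2), "unknown element")
})

test_that("labile hydrogens on O/N/S exchange to deuterium, aliphatic ones do not", {
  ## serine-like fragment: CB-H stays protonated, OG-H exchanges
  atoms <- data.frame(
    name = c("CB", "HB", "OG", "HG"), resn = "SER", resno = 1,
    x = c(0, -1.0, 1.4, 2.1), y = c(0, 0.3, 0, 0.6), z = 0,
    ele = c("C", "H", "O", "H"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(atoms, path)
  b <- neutron_scattering_lengths()
  plain <- read_coordinates(path)
  expect_equal(plain$b[c(2, 4)], rep(unname(b["H"]), 2))
  deut <- read_coordinates(path, deuterate_labile = TRUE)
  expect_equal(deut$b[2], unname(b["H"]))   # bonded to carbon: unchanged
  expect_equal(deut$b[4], unname(b["D"]))   # hydroxyl H: exchanged
})

test_that("residue coarse-graining sums b at the b-weighted centroid", {
  atoms <- data.frame(
    name = c("N", "CA", "N", "CA"), resn = "GLY", resno = c(1, 1, 2, 2),
    x = c(0, 2, 10, 12), y = 0, z = 0, ele = c("N", "C", "N", "C"),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(atoms, path)
  cg <- read_coordinates(path, coarse_grain = TRUE)
  b <- neutron_scattering_lengths()
  bt <- unname(b["N"] + b["C"])
  expect_equal(nrow(cg), 2)
  expect_equal(cg$b, rep(bt, 2))
  expect_equal(cg$x[1], (b[["N"]] * 0 + b[["C"]] * 2) / bt)
})

test_that("form factor equals the closed-form Debye expressions", {
  b <- 6.671
  one <- scattering_centers(matrix(c(0, 0, 0), 1), b)
  q <- seq(0.01, 0.5, by = 0.01)
  expect_equal(form_factor(one, q)$F, rep(b^2, length(q)))
  d <- 20
  two <- scattering_centers(rbind(c(0, 0, 0), c(d, 0, 0)), c(b, b))
  expect_equal(form_factor(two, q)$F,
               2 * b^2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  expect_equal(form_factor(two, 1e-9)$F, (2 * b)^2, tolerance = 1e-9)
})

test_that("rigid-body D0(q) has exact isotropic and low-q limits", {
  fx <- fixture_registry()
  ctr <- fx$coordinates$tetrahedron
  Dtt <- diag(c(rep(2.0, 3), rep(0, 3)))
  sys <- rigid_body_system(ctr, Dtt)
  out <- rigid_body_Dq(sys, c(0.02, 0.1, 0.3), n_orientations = 100)
  expect_equal(out$D0, rep(2.0, 3), tolerance = 1e-10)
  ## anisotropic translation at q -> 0 gives trace(Dtt)/3 on a centered body
  Dan <- diag(c(1, 2, 3, 0, 0, 0))
  sys2 <- rigid_body_system(ctr, Dan)
  out2 <- rigid_body_Dq(sys2, 1e-4, n_orientations = 2000)
  expect_equal(out2$D0, 2, tolerance = 1e-3)
  ## rotation adds apparent mobility for off-origin scattering centers
  Drot <- diag(c(rep(2.0, 3), rep(0.01, 3)))
  sys3 <- rigid_body_system(ctr, Drot)
  out3 <- rigid_body_Dq(sys3, c(0.1, 0.2), n_orientations = 200)
  expect_true(all(out3$D0 > 2.0))
})

test_that("quadrature orientation average matches Monte Carlo within 0.5%", {
  fx <- fixture_registry()
  ctr <- fx$coordinates$dumbbell
  Dmat <- fx$diffusion_matrices$axial_dumbbell
  sys <- rigid_body_system(ctr, Dmat)
  q <- c(0.08, 0.15, 0.25)
  quad <- rigid_body_Dq(sys, q, n_orientations = 500)
  xyz <- as.matrix(ctr[, c("x", "y", "z")])
  mc <- mc_rigid_Dq(xyz, ctr$b, Dmat, q, n_mc = 1e5, seed = TEST_SEED)
  expect_lt(max(abs(quad$D0 / mc - 1)), 0.005)
})

test_that("elastic network has a clean rigid-body null space", {
  fx <- fixture_registry()
  m <- enm_modes(fx$coordinates$compact20, cutoff = 13)
  expect_equal(m$mode_numbers[1], 7)
  expect_gt(m$eigenvalues[1], 0)
  ## eigenvectors orthonormal under the uniform mass weighting
  G <- crossprod(m$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_true(all(m$amplitudes > 0))
  ## two beads, one spring: the single stretch frequency is 2k/m
  two <- scattering_centers(rbind(c(0, 0, 0), c(5, 0, 0)), c(1, 1))
  m2 <- enm_modes(two, cutoff = 6, spring_constant = 3)
  expect_equal(length(m2$eigenvalues), 1)
  expect_equal(m2$eigenvalues[1], 2 * 3, tolerance = 1e-10)
  ## disconnected network is rejected with advice
  far <- scattering_centers(rbind(c(0, 0, 0), c(0, 0, 100), c(3, 0, 0),
                                  c(0, 3, 0)), rep(1, 4))
  expect_error(enm_modes(far, cutoff = 10), "cutoff")
})

test_that("mode-specific diffusion has analytic limits and matches Monte Carlo", {
  fx <- fixture_registry()
  ctr <- fx$coordinates$tetrahedron
  q <- c(0.08, 0.2)
  ## zero amplitude contributes nothing
  ev <- rep(c(1, 0, 0) / 2, 4)
  z <- mode_effective_diffusion(ctr, ev, lambda_alpha = 2, k_alpha = 0, q = q)
  expect_equal(z$D_alpha, c(0, 0))
  ## single center with a unit displacement: lambda k / 3, q-independent
  one <- scattering_centers(matrix(0, 1, 3), 5)
  o <- mode_effective_diffusion(one, c(0, 0, 1), lambda_alpha = 1.5,
                                k_alpha = 2, q = q, n_orientations = 4000)
  expect_equal(o$D_alpha, rep(1.5 * 2 / 3, 2), tolerance = 1e-3)
  ## 4-bead internal mode against the Monte-Carlo double-sum oracle
  m <- enm_modes(ctr, cutoff = 30)
  ev7 <- m$eigenvectors[, 1]
  quad <- mode_effective_diffusion(ctr, ev7, 1, m$amplitudes[1], q,
                                   n_orientations = 500)
  xyz <- as.matrix(ctr[, c("x", "y", "z")])
  mc <- mc_mode_Dq(xyz, ctr$b, matrix(ev7, ncol = 3, byrow = TRUE),
                   1, m$amplitudes[1], q, n_mc = 1e5, seed = TEST_SEED)
  expect_lt(max(abs(quad$D_alpha / mc - 1)), 0.005)
  ## invariance under a global sign flip of the eigenvector
  flip <- mode_effective_diffusion(ctr, -ev7, 1, m$amplitudes[1], q,
                                   n_orientations = 500)
  expect_equal(quad$D_alpha, flip$D_alpha, tolerance = 1e-12)
})

test_that("internal-dynamics decomposition recovers injected mode contributions", {
  q <- seq(0.05, 0.2, by = 0.01)
  rigid <- data.frame(q = q, D0 = 2 + 3 * q)
  meas <- structure(data.frame(q = q, D_eff = rigid$D0, sigma = 0.01),
                    class = c("effective_diffusion_curve", "data.frame"))
  res <- internal_dynamics_residual(meas, rigid)
  expect_equal(res$curve$delta_D, rep(0, length(q)))
  meas2 <- meas; meas2$D_eff <- 1.2 * rigid$D0
  res2 <- internal_dynamics_residual(meas2, rigid)
  expect_equal(res2$fractional_contribution, 1 / 6, tolerance = 1e-10)
  ## closure: rigid + scaled mode curve is recovered
  fx <- fixture_registry()
  sys <- rigid_body_system(fx$coordinates$compact20,
                           fx$diffusion_matrices$isotropic)
  rb <- rigid_body_Dq(sys, q, n_orientations = 300)
  m <- enm_modes(fx$coordinates$compact20, cutoff = 13)
  m7 <- mode_effective_diffusion(fx$coordinates$compact20,
                                 m$eigenvectors[, 1], 1, m$amplitudes[1], q,
                                 n_orientations = 300)
  meas3 <- structure(data.frame(q = q, D_eff = rb$D0 + 0.4 * m7$D_alpha,
                                sigma = 0.01),
                     class = c("effective_diffusion_curve", "data.frame"))
  res3 <- internal_dynamics_residual(meas3, rb)
  expect_equal(res3$curve$delta_D, 0.4 * m7$D_alpha, tolerance = 1e-8)
})

test_that("diffusion-matrix text files round-trip and validate", {
  fx <- fixture_registry()
  path <- withr::local_tempfile(fileext = ".dat")
  m <- fx$diffusion_matrices$axial_dumbbell
  writeLines(c("# units = A^2/ns, rad^2/ns",
               apply(m, 1, paste, collapse = " ")), path)
  back <- read_diffusion_matrix(path)
  expect_equal(back, m, ignore_attr = TRUE)
  expect_error(rigid_body_system(fx$coordinates$dumbbell, diag(5)), "6x6")
  asym <- m; asym[1, 2] <- 1
  expect_error(rigid_body_system(fx$coordinates$dumbbell, asym), "symmetric")
  neg <- m; neg[1, 1] <- -1
  expect_error(rigid_body_system(fx$coordinates$dumbbell, neg),
               "semidefinite")
})
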