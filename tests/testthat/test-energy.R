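# Energy model: closed-form checks, gradient consistency, invariances,
# calibration, and the stability of the designed beta-sheet registry.

test_that("two opposite charges reproduce the Coulomb closed form", {
  q <- 0.43; r <- 3
  tc <- oracle_two_charges(q, r)
  ef <- compute_energy_forces(tc$system, tc$ff)
  rc <- tc$ff$cutoff
  # shifted-force truncation closed form at the working cutoff
  expect_equal(ef$energy,
               -332.0637 * q^2 * (1 / r - 1 / rc + (r - rc) / rc^2),
               tolerance = 1e-10)
  # bare-Coulomb limit as the cutoff grows
  tc$ff$cutoff <- 1e5
  ef2 <- compute_energy_forces(tc$system, tc$ff)
  expect_equal(ef2$energy, -332.0637 * q^2 / 3, tolerance = 1e-3)
})

test_that("forces are the exact negative gradient (central differences)", {
  p <- build_peptide(peptide_spec("AAAA"))
  set.seed(7)
  pos <- p$pos + matrix(rnorm(length(p$pos), 0, 0.08), ncol = 3)
  err <- oracle_grad_error(p, default_forcefield(), pos, n_atoms_check = 17)
  expect_lt(err, 1e-4)
  # periodic solvated case
  w <- fp_waterbox()
  err2 <- oracle_grad_error(w, fp_ff7(), w$pos, n_atoms_check = 8)
  expect_lt(err2, 1e-4)
})

test_that("net force vanishes and energy is rigid-motion invariant", {
  p <- build_peptide(peptide_spec("AAA"))
  ff <- default_forcefield()
  ef <- compute_energy_forces(p, ff)
  fn <- sqrt(sum(ef$forces^2))
  expect_lt(sqrt(sum(colSums(ef$forces)^2)), 1e-8 * max(fn, 1))
  # translation + rotation invariance (vacuum system)
  R <- fibrilpulse:::.rot_axis(c(1, 2, 3), 0.77)
  pos2 <- sweep(p$pos %*% t(R), 2, c(5, -3, 11), "+")
  ef2 <- compute_energy_forces(p, ff, pos2)
  expect_equal(ef2$energy, ef$energy, tolerance = 1e-8)
})

test_that("missing parameters are reported by name", {
  p <- build_peptide(peptide_spec("AA"))
  ff <- default_forcefield()
  ff$lj$CT <- NULL
  expect_error(compute_energy_forces(p, ff), "CT")
  ff <- default_forcefield()
  ff$bonds[["C-O"]] <- NULL
  expect_error(compute_energy_forces(p, ff), "C-O")
})

test_that("C=O stiffness calibration inverts the harmonic relation", {
  # oracle: k = mu (2 pi c nu)^2, mu = mC mO/(mC + mO) = 6.8604 amu
  expect_equal(calibrate_co_stiffness(1680), 1642.6, tolerance = 1e-3)
  expect_equal(calibrate_co_stiffness(2 * 1680),
               4 * calibrate_co_stiffness(1680), tolerance = 1e-12)
  expect_error(calibrate_co_stiffness(0), "positive")
  expect_error(calibrate_co_stiffness(-5), "positive")
})

test_that("minimisation preserves the designed dimer registry", {
  dim2 <- fp_cached("dimer6", build_fibril(fibril_spec(2, 1),
                                           peptide_spec("AAAAAA")))
  d0 <- dim2$registry$d_ON
  m <- minimize_system(dim2, default_forcefield(), maxit = 300)
  d1 <- sqrt(rowSums((m$pos[dim2$registry$O, ] - m$pos[dim2$registry$N, ])^2))
  expect_lt(max(abs(d1 - d0)), 0.3)
})

test_that("force-field text round trip preserves the parameter set", {
  ff <- default_forcefield()
  path <- tempfile(fileext = ".yaml")
  ck <- write_forcefield(ff, path)
  ff2 <- read_forcefield(path)
  expect_equal(ff2$bonds, ff$bonds, tolerance = 1e-8)
  expect_equal(ff2$lj, ff$lj, tolerance = 1e-8)
  expect_equal(ff2$cutoff, ff$cutoff)
  expect_match(ck, "^[0-9a-f]{32}$")
  unlink(path)
})

test_that("force-field validation catches inconsistencies", {
  ff <- default_forcefield()
  ff$bonds[["N-H"]]["k"] <- -1
  expect_error(validate_forcefield(ff), "stiffness")
  ff <- default_forcefield()
  ff$cutoff <- 5
  expect_error(validate_forcefield(ff), "cutoff")
})
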