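# DSSP-criteria secondary structure.

test_that("DSSP energy marks the designed fibril pairs as bonded", {
  f <- fp_fibril12()
  r <- f$registry[1:10, ]
  e <- dssp_hbond_energy(f$pos[r$C, ], f$pos[r$O, ], f$pos[r$N, ],
                         f$pos[r$H, ])
  expect_true(all(e$bonded))
  expect_true(all(e$energy < -0.5))
})

test_that("DSSP energy vanishes as distances grow and rejects r = 0", {
  e <- dssp_hbond_energy(c(0, 0, 0), c(1.23, 0, 0),
                         c(500, 0, 0), c(501, 0, 0))
  expect_false(e$bonded)
  expect_lt(abs(e$energy), 0.01)
  expect_error(dssp_hbond_energy(c(0, 0, 0), c(1, 0, 0),
                                 c(0, 0, 0), c(2, 0, 0)), "coincident")
})

test_that("hand-evaluated four-distance formula matches", {
  C <- c(0, 0, 0); O <- c(1.23, 0, 0); N <- c(4.1, 0.3, 0); H <- c(3.2, 0.2, 0)
  d <- function(a, b) sqrt(sum((a - b)^2))
  ref <- 0.42 * 0.20 * 332 *
    (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
  e <- dssp_hbond_energy(C, O, N, H)
  expect_equal(e$energy, ref, tolerance = 1e-12)
})

test_that("built fibril is intermolecular antiparallel beta, no helix", {
  f <- fp_fibril12()
  ss <- assign_ss(f$pos, f)
  frac <- mean(ss$labels$label == "beta_anti_inter")
  expect_gt(frac, 0.5)
  expect_identical(sum(ss$labels$label == "helix"), 0L)
  # every beta label records a bridge partner
  b <- ss$labels[startsWith(ss$labels$label, "beta"), ]
  expect_true(all(!is.na(b$partner)))
})

test_that("ideal alpha-helix geometry labels interior residues helix", {
  h <- build_peptide(peptide_spec(), phi = -57, psi = -47)
  ss <- assign_ss(h$pos, h)
  interior <- ss$labels$res_local %in% 4:12
  expect_true(all(ss$labels$label[interior] == "helix"))
  expect_false(any(startsWith(ss$labels$label, "beta")))
})

test_that("isolated extended peptides have no secondary structure", {
  p <- build_peptide(peptide_spec())
  ss <- assign_ss(p$pos, p)
  expect_true(all(ss$labels$label == "other"))
})

test_that("missing backbone sites are reported", {
  p <- build_peptide(peptide_spec("AAA"))
  p$resmap$H[3] <- NA_integer_
  expect_error(assign_ss(p$pos, p), "lacks backbone")
})

test_that("ratio series is constant on repeated frames and replica-mean is idempotent", {
  f <- fp_minifibril()
  coords <- array(NA_real_, dim = c(n_atoms(f), 3, 3))
  for (k in 1:3) coords[, , k] <- f$pos
  traj <- structure(list(times = 0:2, coords = coords, box = NA_real_,
                         meta = list(n_atoms = n_atoms(f))),
                    class = "fp_trajectory")
  sr <- ss_ratio_series(traj, f)
  expect_true(all(sr$beta_inter == sr$beta_inter[1]))
  avg <- average_over_replicas(list(sr, sr, sr, sr, sr, sr))
  expect_equal(avg$beta_inter, sr$beta_inter)
  expect_error(average_over_replicas(list(sr, within(sr, time <- time + 1))),
               "time grids")
})

test_that("all fractions lie in [0, 1] on a morphing fixture", {
  f <- fp_minifibril()
  sc <- dissociation_script(duration = 8, stride = 2,
                            morph = data.frame(peptide = 4, t_start = 1,
                                               t_end = 6))
  fx <- generate_fixture(sc, f)
  sr <- ss_ratio_series(fx$trajectory, fx$system)
  frs <- unlist(sr[, -1])
  expect_true(all(frs >= 0 & frs <= 1))
})
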