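# Spectral estimator: synthetic-tone oracles, Parseval, Nyquist guard.

# build a fake 2-atom trajectory whose single C-O bond length is d(t)
fake_bond_traj <- function(dfun, duration_ps = 10, dt_fs = 2) {
  nt <- round(duration_ps * 1000 / dt_fs) + 1
  times <- (seq_len(nt) - 1) * dt_fs / 1000
  coords <- array(0, dim = c(2, 3, nt))
  coords[2, 1, ] <- dfun(times * 1000)  # fs argument
  structure(list(times = times, coords = coords, vels = NULL,
                 box = NA_real_, final = NULL,
                 meta = list(n_atoms = 2)), class = "fp_trajectory")
}

fake_bond_system <- function() {
  at <- data.frame(res_local = 1, res_name = "ALA", site = c("C", "O"),
                   element = c("C", "O"), mass = c(12.011, 15.999),
                   charge = c(0.5, -0.5), heavy = TRUE,
                   lj_type = c("C", "O"), water_affinity = 1,
                   mol_id = 1L, mol_type = "peptide", chain = "A",
                   stringsAsFactors = FALSE)
  fibrilpulse:::fp_system(
    atoms = at, pos = matrix(0, 2, 3),
    bonds = data.frame(i = 1L, j = 2L, type = "C-O"),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        type = character()),
    torsions = data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), type = character()),
    resmap = data.frame())
}

c_cm_fs <- 2.99792458e-5

test_that("bond-velocity series is the analytic derivative of a tone", {
  nu0 <- 1680
  om <- 2 * pi * c_cm_fs * nu0   # rad/fs
  a <- 0.03
  traj <- fake_bond_traj(function(t) 1.23 + a * cos(om * t))
  sys <- fake_bond_system()
  v <- co_stretch_series(traj, sys)
  tt <- (traj$times * 1000)[-c(1, length(traj$times))]
  ref <- -a * om * sin(om * tt)
  # central difference attenuates by sin(om dt)/ (om dt)
  att <- sin(om * 2) / (om * 2)
  expect_equal(as.vector(v), ref * att, tolerance = 1e-6)
})

test_that("a rigidly translated trajectory gives an all-zero series", {
  traj <- fake_bond_traj(function(t) 1.23)
  traj$coords <- traj$coords + rep(seq_along(traj$times), each = 6) * 0.01
  v <- co_stretch_series(traj, fake_bond_system())
  expect_true(all(abs(v) < 1e-12))
})

test_that("C=O bond count equals one per residue including the acetyl cap", {
  p <- build_peptide(peptide_spec())
  expect_identical(sum(p$bonds$type == "C-O"), 14L)  # ACE + 13 Ala
})

test_that("too coarse a stride is rejected citing the Nyquist limit", {
  traj <- fake_bond_traj(function(t) 1.23, dt_fs = 20)
  expect_error(co_stretch_series(traj, fake_bond_system()), "Nyquist")
})

test_that("pure tones are located to within one bin", {
  sys <- fake_bond_system()
  cfg <- spectrum_config(segment_ps = 4)
  for (nu0 in c(1600, 1680, 1777)) {
    om <- 2 * pi * c_cm_fs * nu0
    traj <- fake_bond_traj(function(t) 1.23 + 0.03 * cos(om * t))
    sp <- power_spectrum(co_stretch_series(traj, sys), cfg)
    expect_lte(abs(sp$peak - nu0), sp$bin)
  }
})

test_that("two equal tones give two local maxima within one bin each", {
  om1 <- 2 * pi * c_cm_fs * 1600; om2 <- 2 * pi * c_cm_fs * 1700
  traj <- fake_bond_traj(function(t) 1.23 + 0.02 * cos(om1 * t) +
                           0.02 * cos(om2 * t + 0.4))
  sp <- power_spectrum(co_stretch_series(traj, fake_bond_system()),
                       spectrum_config(segment_ps = 4))
  sel <- which(sp$wavenumber > 1500 & sp$wavenumber < 1800)
  ii <- sp$intensity[sel]
  locmax <- sel[which(ii > c(-Inf, head(ii, -1)) & ii > c(tail(ii, -1), -Inf))]
  peaks <- sp$wavenumber[locmax][order(sp$intensity[locmax],
                                       decreasing = TRUE)][1:2]
  expect_lte(min(abs(peaks - 1600)), sp$bin)
  expect_lte(min(abs(peaks - 1700)), sp$bin)
})

test_that("a zero series yields a flat spectrum flagged with no peak", {
  traj <- fake_bond_traj(function(t) 1.23)
  sp <- power_spectrum(co_stretch_series(traj, fake_bond_system()),
                       spectrum_config(segment_ps = 4))
  expect_true(all(sp$intensity == 0))
  expect_true(is.na(sp$peak))
})

test_that("Parseval: spectral power equals series variance within 1%", {
  set.seed(42)
  n <- 4000; dt <- 2
  x <- as.vector(stats::filter(rnorm(n), rep(1, 8), sides = 1))
  x[is.na(x)] <- 0
  attr(x, "dt_fs") <- dt
  cfg <- spectrum_config(segment_ps = 4, window = "rectangular",
                         overlap = 0)
  sp <- power_spectrum(matrix(x, ncol = 1), cfg, dt_fs = dt)
  M <- round(cfg$segment_ps * 1000 / dt)
  segs <- seq(1, n - M + 1, by = M)
  segvar <- mean(vapply(segs, function(s0) {
    y <- x[s0:(s0 + M - 1)]; mean((y - mean(y))^2)
  }, numeric(1)))
  expect_equal(sum(sp$intensity), segvar, tolerance = 0.01)
})

test_that("tone recovery across the amide-I region, 100 seeded cases", {
  sys <- fake_bond_system()
  cfg <- spectrum_config(segment_ps = 5)
  set.seed(13)
  nus <- runif(100, 1500, 1800)
  fails <- 0
  for (nu0 in nus) {
    om <- 2 * pi * c_cm_fs * nu0
    ph <- runif(1, 0, 2 * pi)
    traj <- fake_bond_traj(function(t) 1.2 + 0.02 * cos(om * t + ph),
                           duration_ps = 10)
    sp <- power_spectrum(co_stretch_series(traj, sys), cfg)
    if (abs(sp$peak - nu0) > sp$bin) fails <- fails + 1
  }
  expect_identical(fails, 0)
})

test_that("peak location is consistent across bin widths", {
  om <- 2 * pi * c_cm_fs * 1680
  traj <- fake_bond_traj(function(t) 1.23 + 0.02 * cos(om * t),
                         duration_ps = 12)
  v <- co_stretch_series(traj, fake_bond_system())
  p5 <- power_spectrum(v, spectrum_config(segment_ps = 5))
  p35 <- power_spectrum(v, spectrum_config(segment_ps = 3.5))
  expect_lte(abs(p5$peak - p35$peak), p35$bin)
})

test_that("spectrum config enforces resolution and coverage", {
  expect_error(spectrum_config(segment_ps = 0.5), "bin width")
  expect_error(spectrum_config(segment_ps = 20, search_range = c(10, 100)),
               "periods")
})
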