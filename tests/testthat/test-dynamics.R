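# Integrator: conservation, thermostat, reproducibility, field coupling.

test_that("microcanonical energy drift is bounded over 10 ps", {
  st <- fp_water_eq()
  nve <- fp_cached("nve10", run_md(st$system, fp_ff7(),
                                   run_config(ensemble = "NVE", seed = 4,
                                              out_stride = 1000,
                                              ene_stride = 25),
                                   duration = 10, velocities = st$vel))
  el <- nve$meta$elog
  etot <- el$kinetic + el$potential
  drift <- abs(stats::coef(stats::lm(etot ~ el$time_fs))[2]) * 1e4
  expect_lt(drift / mean(el$kinetic), 1e-4)   # < 0.01% of mean KE
})

test_that("total linear momentum is conserved without field or thermostat", {
  st <- fp_water_eq()
  nve <- fp_cached("nve10", run_md(st$system, fp_ff7(),
                                   run_config(ensemble = "NVE", seed = 4,
                                              out_stride = 1000,
                                              ene_stride = 25),
                                   duration = 10, velocities = st$vel))
  m <- st$system$atoms$mass
  p0 <- colSums(st$vel * m)
  p1 <- colSums(nve$final$vel * m)
  vn <- sqrt(sum((st$vel * m)^2))
  expect_lt(sqrt(sum((p1 - p0)^2)), 1e-10 * vn)
})

test_that("thermostat holds the mean kinetic temperature near 310 K", {
  st <- fp_water_eq()
  nvt <- fp_cached("nvt12", run_md(st$system, fp_ff7(),
                                   run_config(ensemble = "NVT", seed = 5,
                                              out_stride = 2000,
                                              ene_stride = 100),
                                   duration = 12, velocities = st$vel))
  el <- nvt$meta$elog
  tmean <- mean(el$temperature[el$time_fs > 4000])
  expect_lt(abs(tmean - 310) / 310, 0.02)
})

test_that("a zero-amplitude field is the identity on the trajectory", {
  st <- fp_water_eq()
  cfg <- run_config(ensemble = "NVT", seed = 8, out_stride = 250)
  base <- run_md(st$system, fp_ff7(), cfg, duration = 0.5,
                 velocities = st$vel)
  f0 <- pulse_train(E0 = 0, n_pulses = 2)
  wf <- run_md(st$system, fp_ff7(), cfg, duration = 0.5, field = f0,
               velocities = st$vel)
  expect_identical(base$coords, wf$coords)
  expect_true(all(field_work(wf)$work == 0))
  expect_identical(nrow(field_work(wf)), 2L)
})

test_that("identical config and seed give identical trajectories", {
  w <- fp_waterbox()
  cfg <- run_config(ensemble = "NVT", seed = 17, out_stride = 250)
  a <- run_md(w, fp_ff7(), cfg, duration = 0.5)
  b <- run_md(w, fp_ff7(), cfg, duration = 0.5)
  expect_identical(a$coords, b$coords)
  expect_identical(a$meta$elog, b$meta$elog)
})

test_that("field work on a driven C=O oscillator is largest at resonance", {
  # single carbonyl with opposite partial charges, NVE, polarization x
  at <- data.frame(res_local = 1, res_name = "ALA", site = c("C", "O"),
                   element = c("C", "O"), mass = c(12.011, 15.999),
                   charge = c(0.5, -0.5), heavy = TRUE,
                   lj_type = c("C", "O"), water_affinity = 1,
                   mol_id = 1L, mol_type = "peptide", chain = "A",
                   stringsAsFactors = FALSE)
  sys <- fibrilpulse:::fp_system(
    atoms = at, pos = rbind(c(0, 0, 0), c(1.229, 0, 0)),
    bonds = data.frame(i = 1L, j = 2L, type = "C-O"),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        type = character()),
    torsions = data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), type = character()),
    resmap = data.frame())
  ff <- default_forcefield()
  # the isolated two-body oscillator resonates at the pure closed-form
  # frequency of its calibrated stiffness
  k <- ff$bonds[["C-O"]][["k"]]
  mu <- 12.011 * 15.999 / (12.011 + 15.999)
  nu_res <- sqrt(k * fp_constants$acc / mu) / (2 * pi * fp_constants$c_cm_fs)
  work_at <- function(nu) {
    fld <- pulse_train(E0 = 1e6, sigma = 1, interval = 35, nu = nu,
                       polarization = c(1, 0, 0), n_pulses = 1)
    tr <- run_md(sys, ff, run_config(ensemble = "NVE", seed = 2,
                                     out_stride = 5000),
                 duration = 35, field = fld,
                 velocities = matrix(0, 2, 3))
    sum(field_work(tr)$work)
  }
  expect_gt(work_at(nu_res), 10 * work_at(nu_res + 300))
})

test_that("non-finite energies abort with a diagnostic", {
  w <- fp_waterbox()
  v <- init_velocities(w, 310, 1) * 2000   # absurd velocities -> blow-up
  expect_error(run_md(w, fp_ff7(), run_config(ensemble = "NVE"),
                      duration = 0.2, velocities = v), "aborted")
})

test_that("equilibration barostat relaxes the box volume", {
  w <- fp_waterbox()
  npt <- run_md(w, fp_ff7(), run_config(ensemble = "NPT", seed = 6,
                                        out_stride = 1000, ene_stride = 200,
                                        baro_stride = 100), duration = 2)
  expect_true(is.finite(npt$box))
  expect_gt(npt$box, 10)
  # volume changed at least once
  expect_gt(length(unique(npt$meta$elog$box)), 1L)
})

test_that("trajectory container round-trips with its metadata sidecar", {
  st <- fp_water_eq()
  tr <- run_md(st$system, fp_ff7(),
               run_config(ensemble = "NVT", seed = 9, out_stride = 250),
               duration = 0.5, velocities = st$vel)
  path <- tempfile(fileext = ".traj")
  write_trajectory(tr, path)
  r <- read_trajectory(path)
  expect_identical(r$coords, tr$coords)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$seed, 9L)
  unlink(c(path, paste0(path, ".json")))
})
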