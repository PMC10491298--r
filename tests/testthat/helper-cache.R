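# Session-wide cache so expensive builds/runs are shared across test files.
.fp_test_cache <- new.env(parent = emptyenv())

fp_cached <- function(name, expr) {
  if (!exists(name, envir = .fp_test_cache))
    assign(name, force(expr), envir = .fp_test_cache)
  get(name, envir = .fp_test_cache)
}

# standard small systems
fp_fibril12 <- function() fp_cached("fibril12", build_fibril())

fp_minifibril <- function() fp_cached("minifibril",
  build_fibril(fibril_spec(n_peptides = 4, n_layers = 1),
               peptide_spec("AAAAAA")))

fp_waterbox <- function() fp_cached("waterbox",
  solvate(empty_system(), 125, 15.5, seed = 2))

fp_ff7 <- function() default_forcefield(cutoff = 7)

# equilibrated water box state (positions + velocities)
fp_water_eq <- function() fp_cached("water_eq", {
  w <- fp_waterbox()
  eq <- run_md(w, fp_ff7(), run_config(ensemble = "NVT", seed = 3,
                                       out_stride = 1000), duration = 6)
  w$pos <- eq$final$pos
  list(system = w, vel = eq$final$vel)
})

# --- shared driven-irradiation comparison runs -------------------------
# One equilibrated solvated two-strand sheet; seed-paired control and
# driven trajectories (single pulse at the protocol's field parameters),
# plus a hydrophilic-side-chain variant.  The system is the largest the
# suite's time budget allows; what desk scale can and cannot show about
# driven dissociation is discussed in the methods vignette.
fp_driven_set <- function() fp_cached("driven_set", {
  dim2 <- build_fibril(fibril_spec(n_peptides = 2, n_layers = 1),
                       peptide_spec("AAAA"))
  s0 <- solvate(dim2, 80, 15.5, seed = 5)
  ff <- fp_ff7()
  s <- minimize_system(s0, ff, maxit = 150)
  eq <- run_md(s, ff, run_config(ensemble = "NVT", seed = 31,
                                 out_stride = 2000), duration = 8)
  s$pos <- eq$final$pos
  cfg <- run_config(ensemble = "NVT", seed = 31, out_stride = 1000)
  fld <- pulse_train(nu = 1680, n_pulses = 1)
  ctrl <- run_md(s, ff, cfg, duration = 22, velocities = eq$final$vel)
  driv <- run_md(s, ff, cfg, duration = 22, field = fld,
                 velocities = eq$final$vel)
  ff_hydro <- default_forcefield(cutoff = 7, water_affinity = 2)
  driv_l2 <- run_md(s, ff_hydro, cfg, duration = 22, field = fld,
                    velocities = eq$final$vel)
  list(system = s, field = fld, control = ctrl, driven = driv,
       driven_lambda2 = driv_l2)
})
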