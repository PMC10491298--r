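#' Run configuration for the dynamics engine
#'
#' @param dt Time step, fs (default 0.5; a single time step is used for all
#'   interactions).
#' @param temperature Target temperature, K (default 310).
#' @param tau Thermostat coupling time, ps (single Nose-Hoover thermostat).
#' @param ensemble "NVE", "NVT" or "NPT" (NPT uses stochastic isotropic
#'   volume moves and is intended for equilibration only).
#' @param pressure Target pressure for NPT, MPa.
#' @param seed Integer seed (velocity initialisation and barostat moves).
#' @param out_stride Frame output interval, fs.
#' @param ene_stride Energy-log interval, fs.
#' @param store_velocities Record velocities in the trajectory.
#' @param baro_stride Steps between volume-move attempts (NPT).
#' @return `fp_run_config` object.
#' @export
run_config <- function(dt = 0.5, temperature = 310, tau = 0.1,
                       ensemble = c("NVT", "NVE", "NPT"), pressure = 0.1,
                       seed = 1, out_stride = 50, ene_stride = 50,
                       store_velocities = FALSE, baro_stride = 200) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, temperature > 0, tau > 0, out_stride >= dt)
  structure(list(dt = dt, temperature = temperature, tau = tau,
                 ensemble = ensemble, pressure = pressure, seed = seed,
                 out_stride = out_stride, ene_stride = ene_stride,
                 store_velocities = store_velocities,
                 baro_stride = baro_stride),
            class = "fp_run_config")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities at the given temperature, removes centre-of-mass drift
#' and rescales to the exact target kinetic temperature.
#'
#' @param system `fp_system`.
#' @param temperature K.
#' @param seed Integer seed.
#' @return n x 3 velocity matrix, A/fs.
#' @export
init_velocities <- function(system, temperature = 310, seed = 1) {
  m <- system$atoms$mass
  n <- length(m)
  v <- .with_seed(seed, {
    sd <- sqrt(fp_constants$kB * temperature * fp_constants$acc / m)
    matrix(stats::rnorm(3 * n), n, 3) * sd
  })
  # remove centre-of-mass momentum
  p <- colSums(v * m)
  v <- sweep(v, 2, p / sum(m))
  ke <- 0.5 * sum(m * rowSums(v^2)) / fp_constants$acc
  t_inst <- 2 * ke / ((3 * n - 3) * fp_constants$kB)
  v * sqrt(temperature / t_inst)
}

# pulse spec (ps units) -> engine field list (fs units); NULL -> off
.fp_field_list <- function(field) {
  if (is.null(field)) {
    return(list(on = FALSE, E0 = 0, sigma = 1, interval = 1, omega = 0,
                t0 = 0, n_pulses = 0L, pol = c(0, 0, 1)))
  }
  stopifnot(inherits(field, "fp_pulse_train"))
  list(on = TRUE,
       E0 = field$E0_int,
       sigma = field$sigma * 1000,
       interval = field$interval * 1000,
       omega = field$omega / 1000,     # rad/ps -> rad/fs
       t0 = field$t0_offset * 1000,
       n_pulses = as.integer(field$n_pulses),
       pol = field$polarization)
}

#' Run molecular dynamics
#'
#' Velocity-Verlet integration with optional Nose-Hoover thermostat and an
#' optional electric-field pulse train; every charged site i then feels the
#' additional force q_i E(t) e_pol (a "peptide-only" coupling mode is
#' available through `field_mask`).  Cumulative field work is accumulated
#' per pulse and stored in the trajectory metadata.
#'
#' @param system `fp_system` (solvated or not).
#' @param ff `fp_forcefield`.
#' @param config `fp_run_config`.
#' @param field Optional `fp_pulse_train`.
#' @param velocities Optional starting velocities (defaults to
#'   Maxwell-Boltzmann at the run temperature using the run seed).
#' @param duration Run length, ps.
#' @param field_mask "all" or "peptide".
#' @return `fp_trajectory`.
#' @export
run_md <- function(system, ff, config, duration, field = NULL,
                   velocities = NULL, field_mask = "all") {
  stopifnot(inherits(system, "fp_system"), inherits(config, "fp_run_config"))
  if (is.null(velocities))
    velocities <- init_velocities(system, config$temperature, config$seed)
  top <- .fp_prep_top(system, ff, field_mask = field_mask)
  box <- if (is.na(system$box)) 0 else system$box
  if (box > 0 && ff$cutoff > box / 2)
    stop("cutoff (", ff$cutoff, " A) exceeds half the box (", box / 2, " A)")
  nsteps <- round(duration * 1000 / config$dt)
  out <- cpp_run_md(system$pos, velocities, top, box,
                    config$dt, as.integer(nsteps),
                    as.integer(round(config$out_stride / config$dt)),
                    as.integer(round(config$ene_stride / config$dt)),
                    list(ensemble = config$ensemble,
                         temperature = config$temperature,
                         tau = config$tau * 1000,
                         pressure = config$pressure * 1.4393e-5,  # MPa -> kcal/mol/A^3
                         baro_stride = as.integer(config$baro_stride)),
                    .fp_field_list(field),
                    config$store_velocities, as.integer(config$seed))
  if (!identical(out$status, "ok")) {
    stop("dynamics aborted (", out$status, ") at frame ", out$n_frames,
         "; last energies: ",
         paste(signif(out$elog[max(1, out$n_elog), 2:3], 5), collapse = " / "))
  }
  nf <- out$n_frames
  n <- n_atoms(system)
  coords <- array(out$frames[, seq_len(nf)], dim = c(3, n, nf))
  coords <- aperm(coords, c(2, 1, 3))
  el <- out$elog[seq_len(out$n_elog), , drop = FALSE]
  colnames(el) <- c("time_fs", "kinetic", "potential", "temperature",
                    "bonded", "nonbonded", "conserved", "box")
  traj <- list(
    times = out$times[seq_len(nf)] / 1000,   # ps
    coords = coords,
    vels = if (config$store_velocities)
      aperm(array(out$vels[, seq_len(nf)], dim = c(3, n, nf)), c(2, 1, 3))
      else NULL,
    box = if (out$box > 0) out$box else NA_real_,
    final = list(pos = out$pos, vel = out$vel),
    meta = list(config = unclass(config),
                field = if (!is.null(field)) unclass(field) else NULL,
                field_mask = field_mask,
                work = if (!is.null(field)) out$work else NULL,
                elog = as.data.frame(el),
                seed = config$seed,
                n_atoms = n))
  class(traj) <- "fp_trajectory"
  traj
}

#' @export
print.fp_trajectory <- function(x, ...) {
  cat("fp_trajectory:", length(x$times), "frames x", x$meta$n_atoms,
      "atoms |", signif(utils::tail(x$times, 1), 5), "ps |",
      if (is.null(x$meta$field)) "no field" else
        paste0(x$meta$field$n_pulses, "-pulse field"), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj `fp_trajectory`.
#' @return Integer.
#' @export
n_frames <- function(traj) length(traj$times)

#' Extract one frame's coordinates
#' @param traj `fp_trajectory`.
#' @param i Frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i]
}

#' Field work absorbed per pulse
#'
#' Energy deposited by the electric-field pulse train, accumulated per
#' pulse during the run (integral of F.v over the atoms the field acts on).
#'
#' @param traj `fp_trajectory` recorded with a field.
#' @return data.frame with `pulse` and `work` (kcal/mol).
#' @export
field_work <- function(traj) {
  w <- traj$meta$work
  if (is.null(w))
    stop("trajectory has no field-work accumulator (run without field?)")
  data.frame(pulse = seq_along(w), work = w)
}

#' Write / read a trajectory container
#'
#' The trajectory is stored as a serialized R container (portable RDS,
#' versioned) with a JSON metadata sidecar carrying the run configuration,
#' field spec, seed and per-pulse work, so any published output can be
#' regenerated from its metadata.
#'
#' @param traj `fp_trajectory`.
#' @param path Output path (e.g. "run.traj"); the sidecar is `path`.json.
#' @return `read_trajectory` returns the `fp_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  meta <- traj$meta[c("config", "field", "seed", "work", "field_mask")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  if (!inherits(traj, "fp_trajectory")) stop("not a trajectory container: ", path)
  traj
}
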