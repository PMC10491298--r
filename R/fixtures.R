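# Scripted-trajectory fixture generator: geometric puppetry with exactly
# known ground truth (no force field involved), so every analysis module
# can be validated frame-by-frame against truth tables.

#' Dissociation script
#'
#' Declarative schedule for a synthetic trajectory on top of a built
#' fibril:
#' \itemize{
#' \item `detach`: per-peptide detachment (time ps, displacement vector,
#'   A); the displacement must exceed the oligomer cutoff so the peptide
#'   becomes its own cluster.
#' \item `breaks`: per registry-pair irreversible break times (the donor
#'   N-H hydrogen is reflected through its nitrogen, destroying that bond
#'   and only that bond geometrically).
#' \item `water_arrival`: per registry-pair times at which two dedicated
#'   waters teleport to canonical hydrogen-bond geometry at the broken
#'   pair (one donating to the peptide C=O, one accepting from the
#'   flipped N-H).
#' \item `morph`: per-peptide beta -> helix morphs over [t_start, t_end]
#'   (local geometry interpolated between the ideal strand and ideal
#'   alpha-helix dihedrals).
#' }
#'
#' @param duration Trajectory span, ps.
#' @param stride Frame spacing, ps.
#' @param detach data.frame(peptide, time, dx, dy, dz) or NULL.
#' @param breaks data.frame(pair, time) or NULL (pair = registry row).
#' @param water_arrival data.frame(pair, time) or NULL.
#' @param morph data.frame(peptide, t_start, t_end) or NULL.
#' @param seed Integer recorded in the metadata (generation is fully
#'   deterministic).
#' @return `fp_dissociation_script`.
#' @export
dissociation_script <- function(duration, stride = 1, detach = NULL,
                                breaks = NULL, water_arrival = NULL,
                                morph = NULL, seed = 1) {
  stopifnot(duration > 0, stride > 0)
  chk_time <- function(tb, what) {
    if (!is.null(tb) && nrow(tb) && any(tb[[2]] < 0 | tb[[2]] > duration))
      stop(what, " times must lie within [0, duration]")
  }
  chk_time(detach, "detach"); chk_time(breaks, "break")
  chk_time(water_arrival, "water arrival")
  if (!is.null(detach) && nrow(detach)) {
    if (any(duplicated(detach$peptide)))
      stop("conflicting script: peptide detached twice")
    disp <- sqrt(detach$dx^2 + detach$dy^2 + detach$dz^2)
    if (any(disp <= 5))
      stop("detachment displacement must exceed the 5 A oligomer cutoff")
  }
  if (!is.null(morph) && nrow(morph) && any(morph$t_end < morph$t_start))
    stop("morph t_end before t_start")
  structure(list(duration = duration, stride = stride, detach = detach,
                 breaks = breaks, water_arrival = water_arrival,
                 morph = morph, seed = seed),
            class = "fp_dissociation_script")
}

# ideal-geometry morph frames for one peptide (whole-chain phi/psi
# interpolation between strand and alpha-helix), re-centred on a target
# centroid
.morph_peptide <- function(pspec, frac, centroid) {
  phi <- -139 + frac * (-57 - -139)
  psi <- 135 + frac * (-47 - 135)
  p <- build_peptide(pspec, phi = phi, psi = psi)
  sweep(p$pos, 2, centroid - colMeans(p$pos), "+")
}

#' Generate a scripted fixture trajectory with truth tables
#'
#' Builds the frames realizing the script geometrically and the exact
#' per-frame ground truth every analysis must reproduce.
#'
#' @param script `fp_dissociation_script`.
#' @param base `fp_system` from [build_fibril()] (must carry a registry
#'   when `breaks`/`water_arrival` are scripted).
#' @return List: `system` (base plus any fixture waters), `trajectory`
#'   (an `fp_trajectory`), and `truth` with
#'   \itemize{
#'   \item `breaks`: pair, scheduled time, first broken frame;
#'   \item `partitions`: per-frame list of peptide membership vectors;
#'   \item `pep_phase`: per-frame x peptide label ("beta", "detached",
#'     "morphing", "helix");
#'   \item `water`: pair, arrival frame.
#'   }
#' @export
generate_fixture <- function(script, base) {
  stopifnot(inherits(script, "fp_dissociation_script"),
            inherits(base, "fp_system"))
  needs_reg <- (!is.null(script$breaks) && nrow(script$breaks)) ||
    (!is.null(script$water_arrival) && nrow(script$water_arrival))
  if (needs_reg && is.null(base$registry))
    stop("script references registry pairs but the base has no registry")

  times <- seq(0, script$duration, by = script$stride)
  nfr <- length(times)
  peps <- sort(unique(base$atoms$mol_id[base$atoms$mol_type == "peptide"]))
  np <- length(peps)

  # dedicated fixture waters parked far from the fibril
  n_wpairs <- if (!is.null(script$water_arrival)) nrow(script$water_arrival) else 0
  sys <- base
  if (n_wpairs > 0) {
    span <- apply(base$pos, 2, range)
    park0 <- span[2, ] + c(30, 30, 30)
    wpos <- do.call(rbind, lapply(seq_len(2 * n_wpairs), function(wi) {
      O <- park0 + c(4 * wi, 0, 0)
      rbind(O, O + c(0.9572, 0, 0),
            O + 0.9572 * c(cos(.deg2rad(104.52)), sin(.deg2rad(104.52)), 0))
    }))
    sys <- .fp_add_waters(base, wpos, default_templates())
  }
  n <- n_atoms(sys)
  base_pos <- sys$pos

  pspec <- peptide_spec(
    sys$meta$peptide_spec$sequence %||% strrep("A", 13),
    n_cap = sys$meta$peptide_spec$n_cap %||% "ACE",
    c_cap = sys$meta$peptide_spec$c_cap %||% "NME")

  pep_atoms <- lapply(peps, function(p) sys$atoms$id[sys$atoms$mol_id == p &
                                                     sys$atoms$mol_type == "peptide"])
  names(pep_atoms) <- peps

  coords <- array(NA_real_, dim = c(n, 3, nfr))
  phase <- matrix("beta", nfr, np, dimnames = list(NULL, peps))
  partitions <- vector("list", nfr)

  reg <- base$registry
  for (q in seq_len(nfr)) {
    t <- times[q]
    pos <- base_pos

    # morphs
    if (!is.null(script$morph)) for (m in seq_len(nrow(script$morph))) {
      mp <- script$morph[m, ]
      if (t < mp$t_start) next
      frac <- if (t >= mp$t_end) 1 else
        (t - mp$t_start) / max(mp$t_end - mp$t_start, 1e-9)
      ids <- pep_atoms[[as.character(mp$peptide)]]
      pos[ids, ] <- .morph_peptide(pspec, frac, colMeans(base_pos[ids, ]))
      phase[q, as.character(mp$peptide)] <-
        if (frac >= 1) "helix" else "morphing"
    }
    # pair breaks: reflect donor H through N
    if (!is.null(script$breaks)) for (b in seq_len(nrow(script$breaks))) {
      if (t < script$breaks$time[b]) next
      r <- reg[script$breaks$pair[b], ]
      pos[r$H, ] <- 2 * pos[r$N, ] - pos[r$H, ]
    }
    # detachments (override any morph placement shift)
    if (!is.null(script$detach)) for (d in seq_len(nrow(script$detach))) {
      dd <- script$detach[d, ]
      if (t < dd$time) next
      ids <- pep_atoms[[as.character(dd$peptide)]]
      pos[ids, ] <- sweep(pos[ids, , drop = FALSE], 2,
                          c(dd$dx, dd$dy, dd$dz), "+")
      phase[q, as.character(dd$peptide)] <- "detached"
    }
    # water arrivals
    if (!is.null(script$water_arrival))
      for (wv in seq_len(nrow(script$water_arrival))) {
        if (t < script$water_arrival$time[wv]) next
        r <- reg[script$water_arrival$pair[wv], ]
        w1 <- n_atoms(base) + 6 * (wv - 1)   # first atom of water 2wv-1 is w1+1
        # water donating to the peptide C=O: H at 1.9 A from O along O->C(-)
        uco <- .vunit(pos[r$O, ] - pos[r$C, ])
        Hw <- pos[r$O, ] + 1.9 * uco
        Ow <- pos[r$O, ] + (1.9 + 0.9572) * uco
        pos[w1 + 1, ] <- Ow
        pos[w1 + 2, ] <- Hw
        pos[w1 + 3, ] <- Ow + 0.9572 *
          .vunit(.vcross(uco, c(0.21, 0.55, 0.8)))
        # water accepting from the (possibly flipped) N-H
        unh <- .vunit(pos[r$H, ] - pos[r$N, ])
        Ow2 <- pos[r$H, ] + 1.9 * unh
        pos[w1 + 4, ] <- Ow2
        pos[w1 + 5, ] <- Ow2 + 0.9572 * .vunit(.vcross(unh, c(0.8, 0.21, 0.55)))
        pos[w1 + 6, ] <- Ow2 + 0.9572 *
          .vunit(.vcross(unh, c(0.55, 0.8, 0.21)))
      }
    coords[, , q] <- pos

    # truth partition: attached peptides form one cluster, detached are
    # singletons (the script guarantees separation beyond the cutoff)
    det <- if (!is.null(script$detach))
      script$detach$peptide[script$detach$time <= t] else integer(0)
    mem <- stats::setNames(rep(1L, np), peps)
    nxt_id <- 2L
    for (p in det) { mem[as.character(p)] <- nxt_id; nxt_id <- nxt_id + 1L }
    partitions[[q]] <- mem
  }

  truth_breaks <- if (!is.null(script$breaks) && nrow(script$breaks)) {
    data.frame(pair = script$breaks$pair,
               time = script$breaks$time,
               frame = vapply(script$breaks$time, function(tb)
                 which(times >= tb)[1], integer(1)))
  } else data.frame(pair = integer(), time = numeric(), frame = integer())
  truth_water <- if (n_wpairs > 0) {
    data.frame(pair = script$water_arrival$pair,
               time = script$water_arrival$time,
               frame = vapply(script$water_arrival$time, function(tb)
                 which(times >= tb)[1], integer(1)))
  } else data.frame(pair = integer(), time = numeric(), frame = integer())

  traj <- structure(list(times = times, coords = coords, vels = NULL,
                         box = NA_real_, final = NULL,
                         meta = list(fixture = TRUE,
                                     script = unclass(script),
                                     seed = script$seed,
                                     n_atoms = n)),
                    class = "fp_trajectory")
  list(system = sys, trajectory = traj,
       truth = list(breaks = truth_breaks, partitions = partitions,
                    pep_phase = phase, water = truth_water))
}

#' Frames interpolating a peptide between ideal geometries
#'
#' @param pspec `fp_peptide_spec`.
#' @param from,to "beta" or "helix".
#' @param n_frames Number of frames (n_frames = 1 returns the start
#'   geometry unchanged).
#' @return List of coordinate matrices.
#' @export
generate_ss_morph <- function(pspec = peptide_spec(), from = "beta",
                              to = "helix", n_frames = 5) {
  ang <- list(beta = c(-139, 135), helix = c(-57, -47))
  a0 <- ang[[match.arg(from, names(ang))]]
  a1 <- ang[[match.arg(to, names(ang))]]
  fr <- if (n_frames == 1) 0 else seq(0, 1, length.out = n_frames)
  lapply(fr, function(f) {
    a <- a0 + f * (a1 - a0)
    build_peptide(pspec, phi = a[1], psi = a[2])$pos
  })
}
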