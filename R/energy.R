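# Energy/force evaluation: R-side topology preparation for the C++ engine.

# Flatten a system + force field into the arrays the engine consumes.
# field_mask: "all" (field acts on every charged site) or "peptide".
.fp_prep_top <- function(system, ff, field_mask = "all") {
  at <- system$atoms
  n <- nrow(at)
  lj <- ff$lj
  miss <- setdiff(unique(at$lj_type), names(lj))
  if (length(miss))
    stop("missing Lennard-Jones parameters for: ", paste(miss, collapse = ", "))
  eps <- vapply(lj[at$lj_type], function(x) x[["eps"]], numeric(1))
  sig <- vapply(lj[at$lj_type], function(x) x[["sigma"]], numeric(1))
  lam <- at$water_affinity %||% rep(1, n)
  if (!is.null(ff$water_affinity)) lam[at$site == "CB"] <- ff$water_affinity

  lookup <- function(tab, keys, what, ncol_) {
    if (!length(keys)) return(matrix(0, 0, ncol_))
    miss <- setdiff(unique(keys), names(tab))
    if (length(miss))
      stop("missing ", what, " parameters for type(s): ",
           paste(miss, collapse = ", "))
    do.call(rbind, lapply(tab[keys], function(x) unname(x)))
  }
  bonds <- as.matrix(system$bonds[, c("i", "j")]) - 1L
  storage.mode(bonds) <- "integer"
  bond_par <- lookup(ff$bonds, system$bonds$type, "bond", 2)
  angles <- as.matrix(system$angles[, c("i", "j", "k")]) - 1L
  storage.mode(angles) <- "integer"
  angle_par <- lookup(ff$angles, system$angles$type, "angle", 2)
  if (nrow(angle_par)) angle_par[, 2] <- angle_par[, 2] * pi / 180
  if (nrow(system$torsions)) {
    tors <- as.matrix(system$torsions[, c("i", "j", "k", "l")]) - 1L
    tors_par <- lookup(ff$torsions, system$torsions$type, "torsion", 3)
    if (nrow(tors_par)) tors_par[, 3] <- tors_par[, 3] * pi / 180
  } else {
    tors <- matrix(0L, 0, 4); tors_par <- matrix(0, 0, 3)
  }

  ex <- .fp_exclusions(system$bonds[, c("i", "j")], n)

  fm <- if (identical(field_mask, "peptide")) at$mol_type == "peptide"
        else rep(TRUE, n)

  list(mass = at$mass, charge = at$charge, eps = unname(eps),
       sig = unname(sig), lambda = lam,
       mol = as.integer(factor(at$mol_id, levels = unique(at$mol_id))),
       is_cb = at$site == "CB", is_ow = at$site == "OW",
       bonds = bonds, bond_par = bond_par,
       angles = angles, angle_par = angle_par,
       torsions = tors, torsion_par = tors_par,
       excl = rbind(ex$excl, ex$p14), pair14 = ex$p14,
       scale14 = unname(ff$scale14), cutoff = ff$cutoff,
       coulomb = ff$coulomb, field_mask = fm)
}

# 1-2/1-3 exclusions and 1-4 pairs from the bond graph (0-based matrices)
.fp_exclusions <- function(bp, n) {
  nb <- vector("list", n)
  for (r in seq_len(nrow(bp))) {
    i <- bp$i[r]; j <- bp$j[r]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  e12 <- cbind(pmin(bp$i, bp$j), pmax(bp$i, bp$j))
  e13 <- list(); e14 <- list()
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2) {
      cmb <- utils::combn(nbs, 2)
      e13[[length(e13) + 1L]] <- t(cmb)
    }
  }
  e13 <- if (length(e13)) do.call(rbind, e13) else matrix(0L, 0, 2)
  e13 <- cbind(pmin(e13[, 1], e13[, 2]), pmax(e13[, 1], e13[, 2]))
  for (r in seq_len(nrow(bp))) {
    j <- bp$i[r]; k <- bp$j[r]
    a <- setdiff(nb[[j]], k); b <- setdiff(nb[[k]], j)
    if (length(a) && length(b)) {
      g <- expand.grid(a, b)
      g <- g[g[, 1] != g[, 2], , drop = FALSE]
      if (nrow(g)) e14[[length(e14) + 1L]] <- as.matrix(g)
    }
  }
  e14 <- if (length(e14)) do.call(rbind, e14) else matrix(0L, 0, 2)
  if (nrow(e14)) e14 <- cbind(pmin(e14[, 1], e14[, 2]), pmax(e14[, 1], e14[, 2]))
  key <- function(m) m[, 1] * (n + 1) + m[, 2]
  excl <- unique(rbind(e12, e13))
  if (nrow(e14)) {
    e14 <- e14[!duplicated(key(e14)), , drop = FALSE]
    e14 <- e14[!(key(e14) %in% key(excl)), , drop = FALSE]
  }
  list(excl = excl - 1L, p14 = e14 - 1L)
}

#' Potential energy and forces of a system
#'
#' Evaluates the reduced force field: harmonic bonds and angles, cosine
#' torsions, Lennard-Jones (shifted potential) and Coulomb (shifted force)
#' with a single real-space cutoff, 1-2/1-3 exclusions and scaled 1-4
#' interactions.  Forces are the exact negative gradient of the implemented
#' potential.
#'
#' @param system `fp_system`.
#' @param ff `fp_forcefield`.
#' @param pos Optional coordinate matrix overriding the system's.
#' @return List with `energy` (kcal/mol), `terms` (named per-term
#'   breakdown) and `forces` (n x 3 matrix, kcal/mol/A).
#' @export
compute_energy_forces <- function(system, ff = default_forcefield(),
                                  pos = system$pos) {
  stopifnot(inherits(system, "fp_system"))
  if (!all(is.finite(pos))) stop("positions must be finite")
  top <- .fp_prep_top(system, ff)
  box <- if (is.na(system$box)) 0 else system$box
  cpp_energy_forces(pos, top, box)
}

#' Energy-minimise a system
#'
#' L-BFGS-B minimisation of the potential energy over all coordinates,
#' optionally with harmonic positional restraints.
#'
#' @param system `fp_system`.
#' @param ff `fp_forcefield`.
#' @param maxit Maximum L-BFGS-B iterations.
#' @param restrain_k Positional restraint stiffness (kcal/mol/A^2) applied
#'   to the atoms in `restrain_atoms` about their starting positions;
#'   0 disables.
#' @param restrain_atoms Atom ids to restrain (default: all heavy atoms).
#' @return The system with minimised coordinates; the achieved energy in
#'   `meta$minimised_energy`.
#' @export
minimize_system <- function(system, ff = default_forcefield(), maxit = 200,
                            restrain_k = 0, restrain_atoms = NULL) {
  top <- .fp_prep_top(system, ff)
  box <- if (is.na(system$box)) 0 else system$box
  x0 <- as.vector(t(system$pos))
  ref <- system$pos
  if (restrain_k > 0 && is.null(restrain_atoms))
    restrain_atoms <- system$atoms$id[system$atoms$heavy]
  n <- nrow(system$pos)
  fn <- function(x) {
    p <- matrix(x, n, 3, byrow = TRUE)
    e <- cpp_energy_forces(p, top, box)$energy
    if (restrain_k > 0) {
      d <- p[restrain_atoms, , drop = FALSE] - ref[restrain_atoms, , drop = FALSE]
      e <- e + 0.5 * restrain_k * sum(d * d)
    }
    e
  }
  gr <- function(x) {
    p <- matrix(x, n, 3, byrow = TRUE)
    g <- -cpp_energy_forces(p, top, box)$forces
    if (restrain_k > 0) {
      d <- p[restrain_atoms, , drop = FALSE] - ref[restrain_atoms, , drop = FALSE]
      g[restrain_atoms, ] <- g[restrain_atoms, ] + restrain_k * d
    }
    as.vector(t(g))
  }
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  system$pos <- matrix(res$par, n, 3, byrow = TRUE)
  system$meta$minimised_energy <- res$value
  system
}
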