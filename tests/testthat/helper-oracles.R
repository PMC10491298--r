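# Independent oracles kept deliberately separate from the implementation.

# Brute-force oligomer clustering: full all-heavy-atom-pair distance
# matrix (computed here with base outer(), independent of the package's
# distance helpers) + union-find over contacting peptide pairs.
oracle_oligomers <- function(coords, system, cutoff = 5, box = system$box) {
  at <- system$atoms
  sel <- at$mol_type == "peptide" & at$heavy
  ids <- at$id[sel]
  pep <- at$mol_id[sel]
  peps <- sort(unique(pep))
  L <- if (is.null(box) || is.na(box)) NA else box
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(coords[ids, k], coords[ids, k], "-")
    if (!is.na(L)) dk <- dk - L * round(dk / L)
    d2 <- d2 + dk * dk
  }
  contact <- d2 <= cutoff^2
  parent <- stats::setNames(peps, as.character(peps))
  find <- function(x) { while (parent[[as.character(x)]] != x)
    x <- parent[[as.character(x)]]; x }
  hits <- which(contact, arr.ind = TRUE)
  hits <- hits[pep[hits[, 1]] != pep[hits[, 2]], , drop = FALSE]
  for (h in seq_len(nrow(hits))) {
    ra <- find(pep[hits[h, 1]]); rb <- find(pep[hits[h, 2]])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(peps, find, numeric(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# central-difference force check; returns max abs error over sampled atoms
oracle_grad_error <- function(system, ff, pos, n_atoms_check = 12,
                              h = 1e-5, seed = 1) {
  top <- fibrilpulse:::.fp_prep_top(system, ff)
  box <- if (is.na(system$box)) 0 else system$box
  ef <- fibrilpulse:::cpp_energy_forces(pos, top, box)
  maxerr <- 0
  set.seed(seed)
  for (i in sample(nrow(pos), min(n_atoms_check, nrow(pos)))) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    e1 <- fibrilpulse:::cpp_energy_forces(pp, top, box)$energy
    pp[i, d] <- pp[i, d] - 2 * h
    e2 <- fibrilpulse:::cpp_energy_forces(pp, top, box)$energy
    maxerr <- max(maxerr, abs(-(e1 - e2) / (2 * h) - ef$forces[i, d]))
  }
  maxerr
}

# two-atom "system" with arbitrary charges and no LJ, for closed-form
# Coulomb checks
oracle_two_charges <- function(q, r) {
  at <- data.frame(res_local = 1:2, res_name = "ION", site = c("P1", "P2"),
                   element = "C", mass = 12.011, charge = c(q, -q),
                   heavy = TRUE, lj_type = "P", water_affinity = 1,
                   mol_id = 1:2, mol_type = "peptide", chain = c("A", "B"),
                   stringsAsFactors = FALSE)
  sys <- fibrilpulse:::fp_system(
    atoms = at, pos = rbind(c(0, 0, 0), c(r, 0, 0)),
    bonds = data.frame(i = integer(), j = integer(), type = character()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        type = character()),
    torsions = data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), type = character()),
    resmap = data.frame())
  ff <- default_forcefield()
  ff$lj$P <- c(eps = 0, sigma = 1)
  list(system = sys, ff = ff)
}
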