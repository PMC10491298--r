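# Fibril assembly: antiparallel beta-sheet layers from ideal strands, and
# lattice solvation with three-site water.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# cross-strand O...N hydrogen-bond candidates between two placed strands.
# Returns one row per candidate bond (donor N-H on one strand, acceptor C=O
# on the other), restricted to pairs within [dmin, dmax].
.registry_between <- function(posA, rmA, posB, rmB, dmin = 2.5, dmax = 3.5) {
  out <- list()
  scan <- function(posO, rmO, posN, rmN, dir) {
    accept <- which(!is.na(rmO$O))
    donor <- which(!is.na(rmN$H))
    O <- posO[rmO$O[accept], , drop = FALSE]
    N <- posN[rmN$N[donor], , drop = FALSE]
    d <- .dist_pbc(O, N, NA)
    hit <- which(d >= dmin & d <= dmax, arr.ind = TRUE)
    if (nrow(hit)) {
      ra <- accept[hit[, 1]]; rd <- donor[hit[, 2]]
      data.frame(dir = dir, acc_res = ra, don_res = rd,
                 d_ON = d[hit], stringsAsFactors = FALSE)
    } else NULL
  }
  ab <- scan(posA, rmA, posB, rmB, "A->B")   # acceptor on A, donor on B
  ba <- scan(posB, rmB, posA, rmA, "B->A")
  rbind(ab, ba)
}

#' Assemble an antiparallel beta-sheet fibril from capped peptides
#'
#' Strands are placed in the xy plane: the strand repeat axis along x,
#' adjacent strands antiparallel (rotated 180 degrees about z) and offset by
#' `strand_spacing` along y.  The along-strand offset of the antiparallel
#' neighbour is chosen by a deterministic grid scan followed by a local
#' rigid-body refinement that maximises the number of cross-strand
#' O...H-N contacts with donor-acceptor (O...N) distances near 2.95
#' Angstrom, giving a geometrically plausible in-register hydrogen-bond
#' registry.  Layers are stacked along z at `layer_spacing`, offset by half
#' a strand repeat along x so the alanine side chains interdigitate.
#'
#' @param fspec `fp_fibril_spec`.
#' @param pspec `fp_peptide_spec`.
#' @return `fp_system` with `registry` listing the designed inter-strand
#'   hydrogen bonds (donor peptide/residue, acceptor peptide/residue, the
#'   N, H, C, O atom ids, and the O...N distance).
#' @export
build_fibril <- function(fspec = fibril_spec(), pspec = peptide_spec()) {
  if (!inherits(fspec, "fp_fibril_spec")) stop("fspec must be an fp_fibril_spec")
  if (!inherits(pspec, "fp_peptide_spec")) stop("pspec must be an fp_peptide_spec")
  core <- .build_peptide_core(pspec)
  posA <- .orient_strand(core$pos, core$resmap)
  rm0 <- core$resmap
  Rz <- .rot_axis(c(0, 0, 1), pi)

  # strand repeat length along x (2-residue period)
  ca <- rm0$CA[!is.na(rm0$CA)]
  rep_x <- mean(posA[ca[-(1:2)], 1] - posA[ca[seq_len(length(ca) - 2)], 1])

  # Rigid-body interaction energy (Coulomb + Lennard-Jones, no cutoff)
  # between two placed strand copies.  The physics scores hydrogen bonding
  # and steric packing on the same footing, so the placement search needs
  # no ad-hoc clash penalties.
  ffp <- default_forcefield()
  eps1 <- vapply(ffp$lj[core$atoms$lj_type], function(x) x[["eps"]], numeric(1))
  sig1 <- vapply(ffp$lj[core$atoms$lj_type], function(x) x[["sigma"]], numeric(1))
  qq <- outer(core$atoms$charge, core$atoms$charge) * fp_constants$coulomb
  eij <- sqrt(outer(eps1, eps1))
  sij <- outer(sig1, sig1, "+") / 2
  pair_energy <- function(pa, pb) {
    d <- .dist_pbc(pa, pb, NA)
    x6 <- (sij / d)^6
    sum(qq / d + 4 * eij * (x6 * x6 - x6))
  }

  # --- place the antiparallel neighbour ---
  # The strand template may roll about its axis so the alanine side chains
  # tip out of the sheet plane; roll, along-axis offset, spacing adjustment
  # and in-plane rotation are optimised jointly: a coarse grid keeps the
  # configurations with the most in-band O...N registry contacts, the
  # interaction energy ranks those, and a bounded quasi-Newton refinement
  # polishes the winner.
  rolled <- function(roll) posA %*% t(.rot_axis(c(1, 0, 0), roll))
  place_B <- function(pA, par) {
    # par = (dx, dy, theta_z)
    p <- pA %*% t(.rot_axis(c(0, 0, 1), pi + par[3]))
    sweep(p, 2, c(par[1], fspec$strand_spacing + par[2], 0), "+")
  }
  nbonds <- function(pA, pB) {
    reg <- .registry_between(pA, rm0, pB, rm0, 2.6, 3.35)
    if (is.null(reg)) 0L else nrow(reg)
  }
  grid <- seq(-rep_x, rep_x, by = 0.25)
  rolls <- .deg2rad(seq(-40, 40, by = 10))
  cand <- expand.grid(dx = grid, dy = c(-0.4, 0, 0.4), roll = rolls)
  cnt <- numeric(nrow(cand)); en <- numeric(nrow(cand))
  for (q in seq_len(nrow(cand))) {
    pA <- rolled(cand$roll[q])
    pB <- place_B(pA, c(cand$dx[q], cand$dy[q], 0))
    cnt[q] <- nbonds(pA, pB)
    en[q] <- pair_energy(pA, pB)
  }
  ok <- which(en < 0)
  if (!length(ok)) stop("no attractive inter-strand placement found")
  keep <- ok[cnt[ok] >= max(cnt[ok]) - 1]
  best <- keep[which.min(en[keep])]
  par0 <- c(cand$dx[best], cand$dy[best], 0, cand$roll[best])
  ref <- stats::optim(par0, function(p) {
    pA <- rolled(p[4]); pair_energy(pA, place_B(pA, p[1:3]))
  }, method = "L-BFGS-B",
     lower = par0 - c(0.5, 0.6, 0.05, 0.15),
     upper = par0 + c(0.5, 0.8, 0.05, 0.15),
     control = list(maxit = 200))
  posA <- rolled(ref$par[4])
  posB <- place_B(posA, ref$par[1:3])

  # --- optimise the two-strand lattice vector so the alternate (wide-pair)
  # interface B->C is hydrogen-bonded as well ---
  place_C <- function(par2)
    sweep(posA, 2, c(par2[1], 2 * fspec$strand_spacing + par2[2], 0), "+")
  cand2 <- expand.grid(dx = grid, dy = seq(-0.8, 0.8, by = 0.4))
  cnt2 <- vapply(seq_len(nrow(cand2)), function(q)
    nbonds(posB, place_C(c(cand2$dx[q], cand2$dy[q]))), numeric(1))
  en2 <- vapply(seq_len(nrow(cand2)), function(q)
    pair_energy(posB, place_C(c(cand2$dx[q], cand2$dy[q]))), numeric(1))
  ok2 <- which(en2 < 0)
  if (!length(ok2)) stop("no attractive lattice placement found")
  keep2 <- ok2[cnt2[ok2] >= max(cnt2[ok2]) - 1]
  best2 <- keep2[which.min(en2[keep2])]
  p20 <- c(cand2$dx[best2], cand2$dy[best2])
  ref2 <- stats::optim(p20, function(p) pair_energy(posB, place_C(p)),
                       method = "L-BFGS-B",
                       lower = p20 - c(0.5, 0.6), upper = p20 + c(0.5, 0.8),
                       control = list(maxit = 200))
  lat <- c(ref2$par[1], 2 * fspec$strand_spacing + ref2$par[2], 0)

  # --- layer stacking offset: slide the upper sheet along the strand axis
  # to the lowest-energy position at the fixed layer spacing ---
  xoffs <- seq(0, rep_x, by = 0.25)
  two <- rbind(posA, posB)
  qq2 <- outer(c(core$atoms$charge, core$atoms$charge),
               c(core$atoms$charge, core$atoms$charge)) * fp_constants$coulomb
  eij2 <- sqrt(outer(c(eps1, eps1), c(eps1, eps1)))
  sij2 <- outer(c(sig1, sig1), c(sig1, sig1), "+") / 2
  en_l <- vapply(xoffs, function(xo) {
    d <- .dist_pbc(two, sweep(two, 2, c(xo, 0, fspec$layer_spacing), "+"), NA)
    x6 <- (sij2 / d)^6
    sum(qq2 / d + 4 * eij2 * (x6 * x6 - x6))
  }, numeric(1))
  layer_xoff <- xoffs[which.min(en_l)]

  # --- replicate strands and layers ---
  n_per_layer <- fspec$n_peptides / fspec$n_layers
  n1 <- nrow(posA)
  all_pos <- vector("list", fspec$n_peptides)
  pep <- 0L
  for (l in seq_len(fspec$n_layers) - 1L) {
    shift_l <- c(layer_xoff * l, 0, fspec$layer_spacing * l)
    for (s in seq_len(n_per_layer) - 1L) {
      pep <- pep + 1L
      base <- if (s %% 2L == 0L) posA else posB
      all_pos[[pep]] <- sweep(base, 2, shift_l + (s %/% 2L) * lat, "+")
    }
  }

  # --- assemble atom table and replicated topology ---
  at1 <- core$atoms
  nres1 <- max(rm0$res_local)
  atoms <- do.call(rbind, lapply(seq_len(fspec$n_peptides), function(p) {
    a <- at1
    a$mol_id <- p
    a$mol_type <- "peptide"
    a$chain <- LETTERS[(p - 1L) %% 26L + 1L]
    a
  }))
  pos <- do.call(rbind, all_pos)
  offs <- (seq_len(fspec$n_peptides) - 1L) * n1
  shift_tab <- function(tb, cols) {
    do.call(rbind, lapply(offs, function(o) {
      t2 <- tb
      for (cc in cols) t2[[cc]] <- t2[[cc]] + o
      t2
    }))
  }
  bonds <- shift_tab(core$bonds, c("i", "j"))
  angles <- shift_tab(core$angles, c("i", "j", "k"))
  torsions <- shift_tab(core$torsions, c("i", "j", "k", "l"))
  resmap <- do.call(rbind, lapply(seq_len(fspec$n_peptides), function(p) {
    r <- rm0
    for (s in c("N", "H", "CA", "C", "O", "CB")) r[[s]] <- r[[s]] + offs[p]
    r$mol_id <- p
    r$chain <- LETTERS[(p - 1L) %% 26L + 1L]
    r
  }))

  # --- designed registry across in-layer neighbours ---
  reg <- list()
  pep_of_layer <- matrix(seq_len(fspec$n_peptides), nrow = n_per_layer)
  for (l in seq_len(fspec$n_layers)) {
    peps <- pep_of_layer[, l]
    for (s in seq_len(n_per_layer - 1L)) {
      pa <- peps[s]; pb <- peps[s + 1L]
      rg <- .registry_between(all_pos[[pa]], rm0, all_pos[[pb]], rm0)
      if (is.null(rg) || !nrow(rg)) next
      acc_pep <- ifelse(rg$dir == "A->B", pa, pb)
      don_pep <- ifelse(rg$dir == "A->B", pb, pa)
      reg[[length(reg) + 1L]] <- data.frame(
        don_pep = don_pep, don_res = rg$don_res,
        acc_pep = acc_pep, acc_res = rg$acc_res,
        N = rm0$N[rg$don_res] + offs[don_pep],
        H = rm0$H[rg$don_res] + offs[don_pep],
        C = rm0$C[rg$acc_res] + offs[acc_pep],
        O = rm0$O[rg$acc_res] + offs[acc_pep],
        d_ON = rg$d_ON, stringsAsFactors = FALSE)
    }
  }
  registry <- if (length(reg)) do.call(rbind, reg) else NULL

  sys <- fp_system(atoms = atoms, pos = pos, box = NA_real_, bonds = bonds,
                   angles = angles, torsions = torsions, resmap = resmap,
                   registry = registry,
                   meta = list(fibril_spec = unclass(fspec),
                               peptide_spec = pspec[c("sequence", "n_cap", "c_cap")],
                               neighbour_offset = ref$par,
                               templates = pspec$templates))
  sys
}

#' Solvate a system with three-site water
#'
#' Inserts exactly `n_waters` flexible three-site waters on a jittered cubic
#' lattice inside the box, excluding lattice sites within `exclusion`
#' Angstrom (minimum image) of any peptide heavy atom.  Water orientations
#' are random but seeded, so solvation is fully reproducible.
#'
#' @param system `fp_system` (may be empty of peptides).
#' @param n_waters Number of waters to insert.
#' @param box Cubic box side, Angstrom.
#' @param seed Integer seed for site selection, jitter and orientations.
#' @param exclusion Minimum water-oxygen / peptide-heavy-atom distance.
#' @param templates Residue templates providing the HOH template.
#' @return Solvated `fp_system` with `box` set; the peptide is recentred
#'   into the box.
#' @export
solvate <- function(system, n_waters, box, seed = 1, exclusion = 2.4,
                    templates = default_templates()) {
  stopifnot(inherits(system, "fp_system"), n_waters >= 0, box > 0)
  n0 <- n_atoms(system)
  pos <- system$pos
  if (n0 > 0) {
    # centre solute in the box
    pos <- sweep(pos, 2, colMeans(pos) - box / 2)
  }
  if (n_waters == 0) {
    out <- system
    out$pos <- pos
    out$box <- box
    return(out)
  }

  heavy <- which(system$atoms$heavy & system$atoms$mol_type == "peptide")
  hp <- pos[heavy, , drop = FALSE]

  min_spacing <- 2.75
  n_side <- max(2L, ceiling(n_waters^(1 / 3)))
  sites <- NULL
  repeat {
    spacing <- box / n_side
    if (spacing < min_spacing) {
      ach <- if (is.null(sites)) 0L else nrow(sites)
      stop("box of ", box, " A cannot hold ", n_waters,
           " waters at the ", exclusion, " A exclusion distance; ",
           "achievable count: ", ach)
    }
    g <- (seq_len(n_side) - 0.5) * spacing
    cand <- as.matrix(expand.grid(x = g, y = g, z = g))
    if (length(heavy)) {
      keep <- rep(TRUE, nrow(cand))
      chunk <- 4000L
      for (b in seq(1L, nrow(cand), by = chunk)) {
        ix <- b:min(b + chunk - 1L, nrow(cand))
        d <- .dist_pbc(cand[ix, , drop = FALSE], hp, box)
        keep[ix] <- apply(d, 1, min) > exclusion
      }
      cand <- cand[keep, , drop = FALSE]
    }
    sites <- cand
    if (nrow(sites) >= n_waters) break
    n_side <- n_side + 1L
  }

  tpl <- templates$HOH
  r_OH <- 0.9572
  a_HOH <- .deg2rad(104.52)
  wpos <- .with_seed(seed, {
    pick <- sample.int(nrow(sites), n_waters)
    osite <- sites[pick, , drop = FALSE]
    jit <- min(0.25, (box / n_side - 2.55) / 2)
    if (jit > 0)
      osite <- osite + matrix(stats::runif(3 * n_waters, -jit, jit), ncol = 3)
    out <- matrix(NA_real_, 3 * n_waters, 3)
    for (w in seq_len(n_waters)) {
      # random orthonormal frame
      u <- stats::rnorm(3); u <- .vunit(u)
      v <- stats::rnorm(3); v <- .vunit(v - sum(v * u) * u)
      O <- osite[w, ]
      H1 <- O + r_OH * u
      H2 <- O + r_OH * (cos(a_HOH) * u + sin(a_HOH) * v)
      out[3 * w - 2, ] <- O
      out[3 * w - 1, ] <- H1
      out[3 * w, ] <- H2
    }
    out
  })

  mol0 <- if (n0 > 0) max(system$atoms$mol_id) else 0L
  watoms <- do.call(rbind, lapply(seq_len(n_waters), function(w) {
    s <- tpl$sites
    data.frame(res_local = w, res_name = "HOH", site = s$site,
               element = s$element, mass = s$mass, charge = s$charge,
               heavy = s$heavy, lj_type = s$lj_type, water_affinity = 1,
               mol_id = mol0 + w, mol_type = "water", chain = "W",
               stringsAsFactors = FALSE)
  }))
  watoms <- watoms[names(system$atoms)[names(system$atoms) != "id"]]
  a0 <- system$atoms[names(system$atoms) != "id"]
  atoms <- rbind(a0, watoms)

  ow <- n0 + 3L * (seq_len(n_waters) - 1L) + 1L
  wbonds <- data.frame(i = rep(ow, each = 2), j = c(rbind(ow + 1L, ow + 2L)),
                       type = "OW-HW", stringsAsFactors = FALSE)
  wang <- data.frame(i = ow + 1L, j = ow, k = ow + 2L, type = "HW-OW-HW",
                     stringsAsFactors = FALSE)

  fp_system(atoms = atoms, pos = rbind(pos, wpos), box = box,
            bonds = rbind(system$bonds, wbonds),
            angles = rbind(system$angles, wang),
            torsions = system$torsions, resmap = system$resmap,
            registry = system$registry,
            meta = c(system$meta,
                     list(solvate = list(n_waters = n_waters, seed = seed,
                                         exclusion = exclusion))))
}
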