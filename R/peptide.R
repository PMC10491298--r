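# Single-peptide construction: capped polyalanine in ideal extended
# beta-strand geometry, built by internal-coordinate (NeRF) placement.

# standard bond lengths / angles used for construction (Angstrom / degrees)
.geo <- list(
  b_NH = 1.010, b_NCA = 1.449, b_CAC = 1.522, b_CO = 1.229, b_CN = 1.335,
  b_CH = 1.090, b_CACB = 1.526,
  a_CACN = 116.6, a_CNCA = 121.9, a_NCAC = 110.1, a_CACO = 120.8,
  a_CNH = 119.8, a_XCH = 109.5, a_NCAX = 109.5)

# Build one capped peptide: atom table, coordinates, bonded terms.
# phi/psi are applied to every amino-acid residue (ideal strand or helix).
.build_peptide_core <- function(spec, phi = -139, psi = 135, omega = 180) {
  tpl <- spec$templates
  resnames <- c(spec$n_cap, spec$residues, spec$c_cap)
  nres <- length(resnames)

  # atom table in template order, residue by residue
  at <- do.call(rbind, lapply(seq_along(resnames), function(r) {
    tp <- tpl[[resnames[r]]]
    s <- tp$sites
    data.frame(res_local = r, res_name = resnames[r], site = s$site,
               element = s$element, mass = s$mass, charge = s$charge,
               heavy = s$heavy, lj_type = s$lj_type,
               water_affinity = ifelse(s$site == "CB", tp$water_affinity, 1),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(at)
  # index lookup: idx[[r]][[site]]
  idx <- vector("list", nres)
  off <- 0L
  for (r in seq_len(nres)) {
    sites <- tpl[[resnames[r]]]$sites$site
    idx[[r]] <- as.list(stats::setNames(off + seq_along(sites), sites))
    off <- off + length(sites)
  }

  pos <- matrix(NA_real_, n, 3)
  P <- function(r, s) pos[idx[[r]][[s]], ]
  `P<-` <- function(r, s, value) { pos[idx[[r]][[s]], ] <<- value; pos }
  set <- function(r, s, v) pos[idx[[r]][[s]], ] <<- v
  g <- .geo
  zref <- c(0, 0, 1)

  if (resnames[1] != "ACE") stop("unsupported N-cap: ", resnames[1])
  if (resnames[nres] != "NME") stop("unsupported C-cap: ", resnames[nres])

  # --- ACE cap ---
  set(1, "CH3", c(0, 0, 0))
  set(1, "C", c(g$b_CAC, 0, 0))
  set(1, "O", .place_atom(zref, P(1, "CH3"), P(1, "C"), g$b_CO, g$a_CACO, 90))
  for (h in 1:3)
    set(1, paste0("HH3", h),
        .place_atom(P(1, "O"), P(1, "C"), P(1, "CH3"), g$b_CH, g$a_XCH,
                    60 + 120 * (h - 1)))

  # --- chain residues (amino acids then NME share N placement) ---
  for (r in 2:nres) {
    rp <- r - 1L
    CAp <- if (resnames[rp] == "ACE") "CH3" else "CA"
    # N placed anti to the previous carbonyl O (psi is encoded by placing O
    # of amino residues from the next N, see below; for the residue after
    # ACE the O was placed first, so anti-O gives a planar trans amide)
    if (resnames[rp] == "ACE") {
      set(r, "N", .place_atom(P(rp, "O"), P(rp, CAp), P(rp, "C"),
                              g$b_CN, g$a_CACN, 180))
    } else {
      set(r, "N", .place_atom(P(rp, "N"), P(rp, "CA"), P(rp, "C"),
                              g$b_CN, g$a_CACN, psi))
      # carbonyl O of the previous residue: anti to this N (planar amide)
      set(rp, "O", .place_atom(P(r, "N"), P(rp, "CA"), P(rp, "C"),
                               g$b_CO, g$a_CACO, 180))
    }
    set(r, "H", .place_atom(P(rp, "O"), P(rp, "C"), P(r, "N"),
                            g$b_NH, g$a_CNH, 180))
    if (resnames[r] == "NME") {
      set(r, "CH3", .place_atom(P(rp, CAp), P(rp, "C"), P(r, "N"),
                                g$b_NCA, g$a_CNCA, omega))
      for (h in 1:3)
        set(r, paste0("HH3", h),
            .place_atom(P(rp, "C"), P(r, "N"), P(r, "CH3"), g$b_CH, g$a_XCH,
                        60 + 120 * (h - 1)))
      next
    }
    set(r, "CA", .place_atom(P(rp, CAp), P(rp, "C"), P(r, "N"),
                             g$b_NCA, g$a_CNCA, omega))
    set(r, "C", .place_atom(P(rp, "C"), P(r, "N"), P(r, "CA"),
                            g$b_CAC, g$a_NCAC, phi))
    # provisional O (overwritten once the next N exists; final residue keeps it)
    set(r, "O", .place_atom(P(r, "N"), P(r, "CA"), P(r, "C"),
                            g$b_CO, g$a_CACO, psi + 180))
    # tetrahedral branches at CA: HA and CB mirror across the N-CA-C plane
    uN <- .vunit(P(r, "N") - P(r, "CA"))
    uC <- .vunit(P(r, "C") - P(r, "CA"))
    bis <- -.vunit(uN + uC)
    perp <- .vunit(.vcross(uN, uC))
    ca <- cos(.deg2rad(54.75)); sa <- sin(.deg2rad(54.75))
    set(r, "CB", P(r, "CA") + g$b_CACB * (ca * bis + sa * perp))
    set(r, "HA", P(r, "CA") + g$b_CH * (ca * bis - sa * perp))
    for (h in 1:3)
      set(r, paste0("HB", h),
          .place_atom(P(r, "N"), P(r, "CA"), P(r, "CB"), g$b_CH, g$a_XCH,
                      60 + 120 * (h - 1)))
  }

  # --- bonded terms ---
  bi <- function(r, s) idx[[r]][[s]]
  bonds <- list()
  addb <- function(r1, s1, r2, s2, type)
    bonds[[length(bonds) + 1L]] <<- c(bi(r1, s1), bi(r2, s2), type)
  addb(1, "CH3", 1, "C", "CT-C"); addb(1, "C", 1, "O", "C-O")
  for (h in 1:3) addb(1, "CH3", 1, paste0("HH3", h), "CT-HC")
  for (r in 2:nres) {
    addb(r - 1, "C", r, "N", "C-N")
    addb(r, "N", r, "H", "N-H")
    if (resnames[r] == "NME") {
      addb(r, "N", r, "CH3", "N-CT")
      for (h in 1:3) addb(r, "CH3", r, paste0("HH3", h), "CT-HC")
    } else {
      addb(r, "N", r, "CA", "N-CT")
      addb(r, "CA", r, "HA", "CT-HC")
      addb(r, "CA", r, "CB", "CT-CT")
      for (h in 1:3) addb(r, "CB", r, paste0("HB", h), "CT-HC")
      addb(r, "CA", r, "C", "CT-C")
      addb(r, "C", r, "O", "C-O")
    }
  }
  bonds <- as.data.frame(do.call(rbind, bonds), stringsAsFactors = FALSE)
  names(bonds) <- c("i", "j", "type")
  bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)

  angles <- .angles_from_bonds(bonds[, c("i", "j")], at$lj_type)

  tors <- list()
  addt <- function(a, b, c_, d, type)
    tors[[length(tors) + 1L]] <<- c(a, b, c_, d, type)
  for (r in 2:nres) {
    rp <- r - 1L
    CAp <- if (resnames[rp] == "ACE") "CH3" else "CA"
    CAr <- if (resnames[r] == "NME") "CH3" else "CA"
    addt(bi(rp, CAp), bi(rp, "C"), bi(r, "N"), bi(r, CAr), "omega")
    addt(bi(rp, "O"), bi(rp, "C"), bi(r, "N"), bi(r, "H"), "amide")
    addt(bi(rp, CAp), bi(r, "N"), bi(rp, "C"), bi(rp, "O"), "imp_sp2")
    if (!resnames[r] %in% c("ACE", "NME")) {
      addt(bi(rp, "C"), bi(r, "N"), bi(r, "CA"), bi(r, "C"), "phi")
      if (r < nres)
        addt(bi(r, "N"), bi(r, "CA"), bi(r, "C"), bi(r + 1, "N"), "psi")
    }
  }
  torsions <- as.data.frame(do.call(rbind, tors), stringsAsFactors = FALSE)
  names(torsions) <- c("i", "j", "k", "l", "type")
  for (cc in c("i", "j", "k", "l")) torsions[[cc]] <- as.integer(torsions[[cc]])

  # per-residue backbone map
  resmap <- data.frame(res_local = seq_len(nres), res_name = resnames,
                       stringsAsFactors = FALSE)
  for (s in c("N", "H", "CA", "C", "O", "CB"))
    resmap[[s]] <- vapply(seq_len(nres), function(r) {
      v <- idx[[r]][[s]]; if (is.null(v)) NA_integer_ else as.integer(v)
    }, integer(1))

  list(atoms = at, pos = pos, bonds = bonds, angles = angles,
       torsions = torsions, resmap = resmap)
}

# Rigid-body reorientation into the builder's canonical frame: the mean
# 2-residue repeat vector of the chain along +x, the alternating carbonyl
# direction along +/- y, so sheets assemble in the xy plane.
.orient_strand <- function(pos, resmap) {
  ca <- resmap$CA[!is.na(resmap$CA)]
  ctr <- colMeans(pos)
  if (length(ca) >= 3) {
    reps <- pos[ca[-(1:2)], , drop = FALSE] - pos[ca[seq_len(length(ca) - 2)], , drop = FALSE]
    ax <- .vunit(colMeans(reps))
  } else ax <- c(1, 0, 0)
  amino <- which(!resmap$res_name %in% c("ACE", "NME"))
  sgn <- rep_len(c(1, -1), length(amino))
  co <- sapply(seq_along(amino), function(q) {
    r <- amino[q]
    sgn[q] * (pos[resmap$O[r], ] - pos[resmap$C[r], ])
  })
  v <- rowMeans(co)
  ydir <- .vunit(v - sum(v * ax) * ax)
  zdir <- .vcross(ax, ydir)
  sweep(pos, 2, ctr) %*% cbind(ax, ydir, zdir)
}

# enumerate i-j-k angles from the bond list, typed by canonical lj triples
.angles_from_bonds <- function(bp, lj) {
  nb <- split(c(bp$j, bp$i), c(bp$i, bp$j))
  out <- list()
  for (j in as.integer(names(nb))) {
    nbrs <- sort(nb[[as.character(j)]])
    if (length(nbrs) < 2) next
    cmb <- utils::combn(nbrs, 2)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1, q]; k <- cmb[2, q]
      t1 <- lj[i]; t2 <- lj[k]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; tmp <- i; i <- k; k <- tmp }
      out[[length(out) + 1L]] <- list(i = i, j = j, k = k,
                                      type = paste(t1, lj[j], t2, sep = "-"))
    }
  }
  ang <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  ang$i <- as.integer(ang$i); ang$j <- as.integer(ang$j)
  ang$k <- as.integer(ang$k)
  ang
}

#' Build a capped peptide in ideal strand (or helix) geometry
#'
#' Constructs the peptide's atoms by internal-coordinate placement with
#' every amino-acid residue at the given backbone dihedrals.  The default
#' (phi, psi) = (-139, +135) degrees is the ideal antiparallel beta-strand
#' conformation; (-57, -47) gives an ideal alpha-helix.
#'
#' @param spec `fp_peptide_spec`.
#' @param phi,psi Backbone dihedrals in degrees applied to all residues.
#' @return `fp_system` with a single peptide chain and no box.
#' @examples
#' p <- build_peptide(peptide_spec())
#' n_atoms(p)  # 142 for ACE-(Ala)13-NME
#' @export
build_peptide <- function(spec, phi = -139, psi = 135) {
  if (!inherits(spec, "fp_peptide_spec")) stop("spec must be an fp_peptide_spec")
  core <- .build_peptide_core(spec, phi = phi, psi = psi)
  core$pos <- .orient_strand(core$pos, core$resmap)
  at <- core$atoms
  at$mol_id <- 1L
  at$mol_type <- "peptide"
  at$chain <- "A"
  rm_ <- core$resmap
  rm_$mol_id <- 1L
  rm_$chain <- "A"
  fp_system(atoms = at, pos = core$pos, box = NA_real_, bonds = core$bonds,
            angles = core$angles, torsions = core$torsions, resmap = rm_,
            meta = list(peptide_spec = spec[c("sequence", "n_cap", "c_cap")],
                        phi = phi, psi = psi))
}
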