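# PDB (v3.3 fixed-column) structure I/O, via bio3d.  One chain per
# peptide, waters as HOH in chain W, cubic box on a CRYST1 record.

.pdb_site_out <- c(OW = "O", HW1 = "H1", HW2 = "H2")
.pdb_site_in <- c(O = "OW", H1 = "HW1", H2 = "HW2")

#' Write a system as a PDB file
#'
#' Fixed-column PDB with one chain identifier per peptide (A, B, ...),
#' residues numbered 1-based within each chain, waters as HOH residues in
#' chain W, and the cubic box (if any) on a CRYST1 record.  Coordinates
#' are written as stored (unwrapped).
#'
#' @param system `fp_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path) {
  at <- system$atoms
  n <- nrow(at)
  elety <- at$site
  w <- at$res_name == "HOH"
  elety[w] <- .pdb_site_out[elety[w]]
  type <- ifelse(w, "HETATM", "ATOM")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(system$pos)),
                   type = type,
                   resno = at$res_local,
                   resid = at$res_name,
                   eleno = seq_len(n),
                   elety = elety,
                   chain = at$chain,
                   elesy = at$element)
  if (!is.na(system$box)) {
    lines <- readLines(path)
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     system$box, system$box, system$box, 90, 90, 90)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

#' Read a system from a PDB file
#'
#' Reconstructs the full `fp_system` (atom table with masses, charges and
#' heavy flags from the residue templates, bonded topology regenerated
#' from the per-chain sequences, box from CRYST1).  The designed
#' hydrogen-bond registry is not stored in PDB and is therefore absent
#' from the result.
#'
#' @param path PDB file path.
#' @param templates Residue templates used to restore per-site parameters.
#' @return `fp_system`.
#' @export
read_structure <- function(path, templates = default_templates()) {
  raw <- readLines(path)
  rec <- grepl("^(ATOM|HETATM)", raw)
  bad <- which(rec & nchar(raw) < 54)
  if (length(bad))
    stop("malformed PDB record (missing coordinates) at line ", bad[1])
  for (ln in which(rec)) {
    xyz <- substring(raw[ln], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("unparseable coordinates at line ", ln)
  }
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  box <- NA_real_
  cl <- grep("^CRYST1", raw, value = TRUE)
  if (length(cl)) {
    sides <- as.numeric(substring(cl[1], c(7, 16, 25), c(15, 24, 33)))
    if (all(is.finite(sides)) && max(sides) - min(sides) < 1e-3)
      box <- sides[1]
  }
  site <- a$elety
  w <- a$resid == "HOH"
  site[w] <- .pdb_site_in[site[w]]

  miss <- setdiff(unique(a$resid), names(templates))
  if (length(miss))
    stop("no residue template for: ", paste(miss, collapse = ", "))

  # peptide chains in order of appearance
  chains <- unique(a$chain[!w])
  pep_specs <- lapply(chains, function(ch) {
    sel <- a$chain == ch & !w
    resn <- a$resid[sel][!duplicated(a$resno[sel])]
    resn
  })
  n_waters <- sum(w) / 3

  # rebuild topology per chain (sequence without caps)
  sys <- NULL
  for (ci in seq_along(chains)) {
    resn <- pep_specs[[ci]]
    seq1 <- paste(names(.one_letter)[match(resn[-c(1, length(resn))],
                                           .one_letter)], collapse = "")
    p <- build_peptide(peptide_spec(seq1, n_cap = resn[1],
                                    c_cap = resn[length(resn)],
                                    templates = templates))
    sel <- which(a$chain == chains[ci] & !w)
    if (length(sel) != n_atoms(p))
      stop("chain ", chains[ci], " has ", length(sel),
           " atoms; template topology expects ", n_atoms(p))
    if (!all(p$atoms$site == site[sel]))
      stop("atom order in chain ", chains[ci],
           " does not match the template site order")
    p$pos <- cbind(a$x[sel], a$y[sel], a$z[sel])
    p$atoms$chain <- chains[ci]
    p$resmap$chain <- chains[ci]
    sys <- if (is.null(sys)) p else .fp_merge_peptides(sys, p)
  }
  if (is.null(sys)) {
    sys <- fp_system(atoms = .empty_atoms(), pos = matrix(0, 0, 3),
                     bonds = .empty_bonds(), angles = .empty_angles(),
                     torsions = .empty_torsions(), resmap = data.frame())
  }
  if (n_waters > 0) {
    wsel <- which(w)
    wpos <- cbind(a$x[wsel], a$y[wsel], a$z[wsel])
    sys <- .fp_add_waters(sys, wpos, templates)
  }
  sys$box <- box
  sys
}

# concatenate two single/multi-peptide systems (no waters)
.fp_merge_peptides <- function(s1, s2) {
  off <- n_atoms(s1)
  moff <- max(s1$atoms$mol_id)
  a2 <- s2$atoms
  a2$mol_id <- a2$mol_id + moff
  shift <- function(tb, cols) { for (cc in cols) tb[[cc]] <- tb[[cc]] + off; tb }
  rm2 <- s2$resmap
  for (s in c("N", "H", "CA", "C", "O", "CB")) rm2[[s]] <- rm2[[s]] + off
  rm2$mol_id <- rm2$mol_id + moff
  fp_system(atoms = rbind(s1$atoms[names(s1$atoms) != "id"],
                          a2[names(a2) != "id"]),
            pos = rbind(s1$pos, s2$pos), box = s1$box,
            bonds = rbind(s1$bonds, shift(s2$bonds, c("i", "j"))),
            angles = rbind(s1$angles, shift(s2$angles, c("i", "j", "k"))),
            torsions = rbind(s1$torsions, shift(s2$torsions, c("i", "j", "k", "l"))),
            resmap = rbind(s1$resmap, rm2),
            registry = s1$registry, meta = s1$meta)
}

# append waters with given coordinates (O,H1,H2 triplets)
.fp_add_waters <- function(sys, wpos, templates) {
  n_waters <- nrow(wpos) / 3
  n0 <- n_atoms(sys)
  tpl <- templates$HOH
  mol0 <- if (n0 > 0) max(sys$atoms$mol_id) else 0L
  watoms <- do.call(rbind, lapply(seq_len(n_waters), function(wi) {
    s <- tpl$sites
    data.frame(res_local = wi, res_name = "HOH", site = s$site,
               element = s$element, mass = s$mass, charge = s$charge,
               heavy = s$heavy, lj_type = s$lj_type, water_affinity = 1,
               mol_id = mol0 + wi, mol_type = "water", chain = "W",
               stringsAsFactors = FALSE)
  }))
  ow <- n0 + 3L * (seq_len(n_waters) - 1L) + 1L
  wbonds <- data.frame(i = rep(ow, each = 2), j = c(rbind(ow + 1L, ow + 2L)),
                       type = "OW-HW", stringsAsFactors = FALSE)
  wang <- data.frame(i = ow + 1L, j = ow, k = ow + 2L, type = "HW-OW-HW",
                     stringsAsFactors = FALSE)
  fp_system(atoms = rbind(sys$atoms[names(sys$atoms) != "id"], watoms),
            pos = rbind(sys$pos, wpos), box = sys$box,
            bonds = rbind(sys$bonds, wbonds),
            angles = rbind(sys$angles, wang),
            torsions = sys$torsions, resmap = sys$resmap,
            registry = sys$registry, meta = sys$meta)
}

.empty_atoms <- function() {
  data.frame(res_local = integer(), res_name = character(), site = character(),
             element = character(), mass = numeric(), charge = numeric(),
             heavy = logical(), lj_type = character(),
             water_affinity = numeric(), mol_id = integer(),
             mol_type = character(), chain = character(),
             stringsAsFactors = FALSE)
}
.empty_bonds <- function() data.frame(i = integer(), j = integer(),
                                      type = character())
.empty_angles <- function() data.frame(i = integer(), j = integer(),
                                       k = integer(), type = character())
.empty_torsions <- function() data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         type = character())

#' An empty system (solvent-only starting point)
#' @return `fp_system` with no atoms and no box.
#' @export
empty_system <- function() {
  fp_system(atoms = .empty_atoms(), pos = matrix(0, 0, 3),
            bonds = .empty_bonds(), angles = .empty_angles(),
            torsions = .empty_torsions(), resmap = data.frame())
}
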