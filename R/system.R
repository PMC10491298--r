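#' System model container
#'
#' An `fp_system` bundles everything the energy model and the analyses need:
#' an atom table (identity, site name, mass, charge, heavy-atom flag,
#' Lennard-Jones type), coordinates in Angstrom, the cubic box side (NA for
#' a non-periodic system), bonded terms with type keys, a per-residue
#' backbone site map, and the designed inter-strand hydrogen-bond registry
#' when the system was built as a fibril.
#'
#' Coordinates are stored unwrapped; periodic wrapping is applied on demand
#' (minimum-image convention) by the analyses and the engine.
#'
#' @param atoms data.frame of atom records.
#' @param pos n x 3 coordinate matrix, Angstrom.
#' @param box Cubic box side length in Angstrom, or NA.
#' @param bonds,angles,torsions Bonded term tables with `type` keys.
#' @param resmap Per-residue table mapping backbone/side-chain site names to
#'   atom ids.
#' @param registry Designed inter-strand hydrogen-bond pair table or NULL.
#' @param meta Named list of provenance metadata.
#' @return `fp_system` object.
#' @keywords internal
fp_system <- function(atoms, pos, box = NA_real_, bonds, angles, torsions,
                      resmap, registry = NULL, meta = list()) {
  stopifnot(nrow(atoms) == nrow(pos), ncol(pos) == 3)
  atoms$id <- seq_len(nrow(atoms))
  q <- sum(atoms$charge)
  if (abs(q) > 1e-6)
    stop("system is not charge neutral (net charge ", signif(q, 4), " e)")
  for (tb in list(bonds, angles, torsions)) {
    if (nrow(tb)) {
      cols <- intersect(c("i", "j", "k", "l"), names(tb))
      ix <- unlist(tb[cols], use.names = FALSE)
      if (any(ix < 1L | ix > nrow(atoms)))
        stop("bonded term references a non-existent atom")
    }
  }
  structure(list(atoms = atoms, pos = pos, box = box, bonds = bonds,
                 angles = angles, torsions = torsions, resmap = resmap,
                 registry = registry, meta = meta),
            class = "fp_system")
}

#' @export
print.fp_system <- function(x, ...) {
  np <- length(unique(x$atoms$mol_id[x$atoms$mol_type == "peptide"]))
  nw <- sum(x$atoms$mol_type == "water") / 3
  cat("fp_system:", nrow(x$atoms), "atoms |", np, "peptide(s) |", nw,
      "water(s) | box:",
      if (is.na(x$box)) "none" else paste0(signif(x$box, 6), " A"), "\n")
  invisible(x)
}

#' @export
summary.fp_system <- function(object, ...) {
  print(object)
  cat("  bonds:", nrow(object$bonds), " angles:", nrow(object$angles),
      " torsions:", nrow(object$torsions), "\n")
  cat("  net charge:", signif(sum(object$atoms$charge), 3), "e\n")
  if (!is.null(object$registry))
    cat("  designed inter-strand H-bonds:", nrow(object$registry), "\n")
  invisible(object)
}

#' Number of atoms in a system
#' @param system `fp_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Wrap coordinates into the primary box
#'
#' Returns a copy of the coordinate matrix with every position wrapped into
#' `[0, box)`.  Identity when the system has no box.
#'
#' @param system `fp_system`.
#' @param pos Optional coordinate matrix (defaults to the system's own).
#' @return n x 3 matrix.
#' @export
wrap_positions <- function(system, pos = system$pos) {
  L <- system$box
  if (is.null(L) || is.na(L) || L <= 0) return(pos)
  pos - L * floor(pos / L)
}

# indices of peptide heavy atoms, grouped by peptide
.heavy_by_peptide <- function(system) {
  a <- system$atoms
  sel <- a$mol_type == "peptide" & a$heavy
  split(a$id[sel], a$mol_id[sel])
}
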