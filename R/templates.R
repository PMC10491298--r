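#' Residue site templates
#'
#' A residue template lists the interaction sites of one residue (or cap, or
#' water) of the reduced model: site names, elements, masses, partial charges
#' and heavy-atom flags, plus a unitless side-chain/water affinity scale
#' `water_affinity` (lambda).  Lambda multiplies the Lorentz-Berthelot
#' epsilon between the residue's side-chain carbon sites and water oxygen,
#' turning the hydrophobicity of the side chain into a single tunable
#' parameter (alanine defaults to lambda = 0.5, i.e. hydrophobic).
#'
#' @param name Residue identifier (e.g. "ALA").
#' @param sites data.frame with columns `site`, `element`, `charge`,
#'   `lj_type` (key into the force-field Lennard-Jones table).  Masses are
#'   looked up from the element.
#' @param water_affinity Unitless lambda >= 0 scaling side-chain-water
#'   attraction.
#' @return An object of class `fp_residue_template`.
#' @export
residue_template <- function(name, sites, water_affinity = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  need <- c("site", "element", "charge", "lj_type")
  if (!all(need %in% names(sites)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (water_affinity < 0) stop("water_affinity must be >= 0")
  sites$mass <- unname(.fp_masses[sites$element])
  if (anyNA(sites$mass)) stop("unknown element in residue template ", name)
  if (any(sites$mass <= 0)) stop("site masses must be positive")
  sites$heavy <- sites$element != "H"
  q <- sum(sites$charge)
  if (abs(q - round(q)) > 1e-6)
    stop("net charge of template ", name, " (", signif(q, 4),
         ") is not an integer multiple of e")
  # amino-acid residues must expose the DSSP backbone sites
  if (!name %in% c("ACE", "NME", "HOH")) {
    miss <- setdiff(c("N", "H", "CA", "C", "O"), sites$site)
    if (length(miss))
      stop("residue template ", name, " lacks backbone sites: ",
           paste(miss, collapse = ", "))
  }
  structure(list(name = name, sites = sites, water_affinity = water_affinity),
            class = "fp_residue_template")
}

#' Built-in residue templates
#'
#' Templates for alanine, the acetyl (ACE) and N-methyl (NME) caps, and
#' three-site water.  Partial charges are patterned after standard protein
#' force fields (magnitudes chosen so backbone C=O...H-N hydrogen bonds
#' emerge from electrostatics plus Lennard-Jones, not from an explicit
#' hydrogen-bond term).
#'
#' @return Named list of `fp_residue_template` objects.
#' @export
default_templates <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  ala <- df(
    site    = c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O"),
    element = c("N", "H", "C", "H", "C", "H", "H", "H", "C", "O"),
    charge  = c(-0.4157, 0.2719, 0.0337, 0.0823, -0.1825,
                0.0603, 0.0603, 0.0603, 0.5973, -0.5679),
    lj_type = c("N", "H", "CT", "HC", "CT", "HC", "HC", "HC", "C", "O"))
  ace <- df(
    site    = c("CH3", "HH31", "HH32", "HH33", "C", "O"),
    element = c("C", "H", "H", "H", "C", "O"),
    charge  = c(-0.3662, 0.1123, 0.1123, 0.1123, 0.5972, -0.5679),
    lj_type = c("CT", "HC", "HC", "HC", "C", "O"))
  nme <- df(
    site    = c("N", "H", "CH3", "HH31", "HH32", "HH33"),
    element = c("N", "H", "C", "H", "H", "H"),
    charge  = c(-0.4157, 0.2719, -0.1490, 0.0976, 0.0976, 0.0976),
    lj_type = c("N", "H", "CT", "HC", "HC", "HC"))
  hoh <- df(
    site    = c("OW", "HW1", "HW2"),
    element = c("O", "H", "H"),
    charge  = c(-0.834, 0.417, 0.417),
    lj_type = c("OW", "HW", "HW"))
  list(
    ALA = residue_template("ALA", ala, water_affinity = 0.5),
    ACE = residue_template("ACE", ace),
    NME = residue_template("NME", nme),
    HOH = residue_template("HOH", hoh))
}

.one_letter <- c(A = "ALA")

#' Peptide specification
#'
#' @param sequence One-letter residue string; default is 13 alanines, the
#'   polyalanine model peptide.
#' @param n_cap,c_cap Cap residue names (acetyl / N-methyl amide).
#' @param templates Named list of residue templates.
#' @return `fp_peptide_spec` object.
#' @export
peptide_spec <- function(sequence = strrep("A", 13), n_cap = "ACE",
                         c_cap = "NME", templates = default_templates()) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty one-letter residue string")
  letters1 <- strsplit(sequence, "")[[1]]
  res <- .one_letter[letters1]
  if (anyNA(res)) {
    bad <- unique(letters1[is.na(res)])
    stop("no residue template for: ", paste(bad, collapse = ", "))
  }
  for (r in unique(c(res, n_cap, c_cap)))
    if (is.null(templates[[r]])) stop("no residue template for: ", r)
  structure(list(sequence = sequence, residues = unname(res),
                 n_cap = n_cap, c_cap = c_cap, templates = templates),
            class = "fp_peptide_spec")
}

#' Fibril specification
#'
#' Geometry of the two-layer antiparallel beta-sheet fibril.  The default
#' inter-sheet (layer) spacing of 5.4 Angstrom is the tight sheet-sheet
#' packing distance of polyalanine, which keeps the two sheets within the
#' 5 Angstrom heavy-atom contact cutoff used by the oligomer analysis, as a
#' single intact fibril must be.
#'
#' @param n_peptides Number of peptides (default 12).
#' @param n_layers Number of stacked beta-sheets (default 2).
#' @param arrangement Only "antiparallel" is supported.
#' @param strand_spacing Inter-strand spacing within a sheet, Angstrom.
#' @param layer_spacing Sheet-to-sheet stacking distance, Angstrom.
#' @return `fp_fibril_spec` object.
#' @export
fibril_spec <- function(n_peptides = 12, n_layers = 2,
                        arrangement = "antiparallel",
                        strand_spacing = 4.8, layer_spacing = 5.4) {
  if (n_peptides %% n_layers != 0)
    stop("n_peptides (", n_peptides, ") must be divisible by n_layers (",
         n_layers, ")")
  if (strand_spacing <= 0 || layer_spacing <= 0)
    stop("spacings must be positive")
  arrangement <- match.arg(arrangement, "antiparallel")
  structure(list(n_peptides = n_peptides, n_layers = n_layers,
                 arrangement = arrangement, strand_spacing = strand_spacing,
                 layer_spacing = layer_spacing),
            class = "fp_fibril_spec")
}
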