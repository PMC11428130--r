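## Element data used for bond perception and validity screening.
## Covalent radii are the single-bond values of Cordero et al. (2008);
## for Mn, Fe and Co the low-spin radii are used (the looser metal-donor
## tolerance already captures long dative contacts, and the larger
## high-spin radii would sweep chelate backbone atoms into the donor set).

.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
  Cr = 1.39, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22,
  ## additional d-block metals accepted for transferability inputs
  Sc = 1.70, Ti = 1.60, V = 1.53,
  Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54, Tc = 1.47,
  Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  La = 2.07, Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51,
  Os = 1.44, Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32
)

## The curated element set S (heavy elements; hydrogen is stripped on
## ingest so the 15 remaining symbols define the atom-type vocabulary).
.element_set_heavy <- c(
  "C", "N", "O", "F", "P", "S", "Cl", "Br",
  "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn"
)

.training_metals <- c("Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn")

.dblock_metals <- c(
  .training_metals,
  "Sc", "Ti", "V", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd",
  "Ag", "Cd", "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg"
)

## Maximum plausible connectivity per heavy element once hydrogens are
## stripped (a ligand-internal degree above this fails the valence screen;
## bonds to the metal are dative and not counted).
.max_valence <- c(
  C = 4, N = 4, O = 2, F = 1, P = 6, S = 6, Cl = 1, Br = 1
)

#' Covalent radius lookup
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of covalent radii in Angstrom.
#' @examples
#' covalent_radius(c("C", "Fe"))
#' @export
covalent_radius <- function(elements) {
  r <- .covalent_radii[elements]
  if (anyNA(r)) {
    bad <- unique(elements[is.na(r)])
    stop(tmcdiff_error("unknown_element",
      sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", "))))
  }
  unname(r)
}

#' Is an element a d-block metal accepted as a complex centre?
#' @param elements character vector of element symbols.
#' @return logical vector.
#' @export
is_metal <- function(elements) elements %in% .dblock_metals

#' The heavy-element vocabulary (element set minus hydrogen)
#' @return character vector of 15 element symbols.
#' @export
element_vocabulary <- function() .element_set_heavy

## typed condition constructor used across the package
tmcdiff_error <- function(type, message, call = sys.call(-1)) {
  structure(
    class = c(paste0("tmcdiff_", type), "tmcdiff_error", "error", "condition"),
    list(message = message, call = call)
  )
}
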