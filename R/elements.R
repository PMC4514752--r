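#' Van der Waals radii for common elements
#'
#' Bondi-style van der Waals radii (in Angstrom) for the elements that occur
#' in typical protein-ligand systems. Elements absent from the table fall
#' back to the carbon radius of 1.70 A.
#'
#' @format Named numeric vector, Angstrom.
#' @export
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90
)

#' Look up van der Waals radii by element symbol
#'
#' @param element Character vector of element symbols (case-insensitive in
#'   the PDB sense: "CL" and "Cl" both resolve to chlorine).
#' @return Numeric vector of radii in Angstrom; unknown elements get 1.70 A.
#' @examples
#' vdw_radius(c("C", "N", "O"))
#' @export
vdw_radius <- function(element) {
  elt <- normalize_element(element)
  r <- unname(VDW_RADII[elt])
  r[is.na(r)] <- 1.70
  r
}

# "CL" -> "Cl", "c" -> "C": first letter upper, rest lower
normalize_element <- function(element) {
  elt <- trimws(as.character(element))
  paste0(toupper(substr(elt, 1, 1)), tolower(substr(elt, 2, nchar(elt))))
}

is_hydrogen <- function(element) normalize_element(element) %in% c("H", "D")
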