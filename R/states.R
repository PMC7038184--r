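#' Ramachandran-sign classification of a residue conformation
#'
#' Classifies a (phi, psi) pair by the sign quadrant of the Ramachandran
#' plot: alpha_R ("R") when both angles are strictly negative, alpha_L
#' ("L") when both are strictly positive, "O" (other) for every remaining
#' defined pair -- including the measure-zero boundaries where phi or psi
#' is exactly 0 or +/-180 -- and "U" (undefined) when either dihedral is
#' missing (chain termini, chain breaks, degenerate geometry).
#'
#' The rule is deliberately coarse: alpha-strand detection needs only the
#' sign alternation of successive residues, not helix/sheet region
#' boundaries, so no beta region is defined.
#'
#' @param phi,psi Numeric vectors of dihedrals in degrees, `NA` when
#'   undefined. Values are expected in (-180, 180]; use [wrap_angle()]
#'   first if needed.
#' @return Character vector over `c("R", "L", "O", "U")`.
#' @export
#' @examples
#' classify_state(c(-60, 70, -120, 0, NA), c(-45, 45, 130, -45, -45))
classify_state <- function(phi, psi) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  out <- rep("O", n)
  undef <- is.na(phi) | is.na(psi)
  r <- !undef & phi > -180 & phi < 0 & psi > -180 & psi < 0
  l <- !undef & phi > 0 & phi < 180 & psi > 0 & psi < 180
  out[r] <- "R"
  out[l] <- "L"
  out[undef] <- "U"
  out
}
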