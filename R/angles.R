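#' Wrap angles into the half-open interval (-180, 180]
#'
#' Torsion angles are reported on the standard Ramachandran convention:
#' cis = 0 degrees, trans = 180 degrees, with -180 mapped to +180 so each
#' geometry has a single representative.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, in (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(-181, 190, -180, 360))
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Circular difference between two angles
#'
#' Computes `to - from` on the circle, wrapped through +/-180 so the
#' magnitude is always the shorter arc. Used for peptide-plane flip
#' detection, where a psi change of -45 -> 150 degrees is a 165-degree
#' rotation, not a 195-degree one.
#'
#' @param to,from Numeric vectors of angles in degrees.
#' @return Signed circular difference in (-180, 180].
#' @export
circular_diff <- function(to, from) {
  wrap_angle(to - from)
}

#' Torsion angle of four points
#'
#' Standard torsion (dihedral) angle p1-p2-p3-p4 under the IUPAC sign
#' convention: 0 for cis, 180 for trans, positive for a clockwise rotation
#' of the far bond when viewed from p2 towards p3. Computed with the
#' two-plane-normal atan2 formula, which is free of the acos sign
#' ambiguity.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180], or `NA_real_` when either
#'   atom triple is collinear (cross-product norm below 1e-9) and the
#'   torsion is undefined.
#' @export
#' @examples
#' dihedral_angle(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # -90
dihedral_angle <- function(p1, p2, p3, p4) {
  drop(dihedral_angle_many(
    matrix(p1, 1), matrix(p2, 1), matrix(p3, 1), matrix(p4, 1)
  ))
}

# vectorised torsion over n x 3 coordinate matrices; rows with any NA or a
# degenerate (collinear) triple yield NA
dihedral_angle_many <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nn1 <- sqrt(rowSums(n1^2))
  nn2 <- sqrt(rowSums(n2^2))
  m <- cross3(n1, n2)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m * b2) / b2n
  ang <- wrap_angle(atan2(y, x) * 180 / pi)
  ang[!is.na(nn1) & (nn1 < 1e-9 | nn2 < 1e-9)] <- NA_real_
  ang
}

cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}
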