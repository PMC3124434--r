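# Pure coordinate mathematics: signed dihedrals, point reflection,
# internal-coordinate atom placement.  Positions are numeric length-3
# vectors in Angstrom.

# Cross-product norm below this (A^2) means a collinear/coincident frame.
.COLLINEAR_TOL <- 1e-10

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(a) sqrt(sum(a * a))

.check_vec3 <- function(p, what) {
  if (!is.numeric(p) || length(p) != 3L || !all(is.finite(p)))
    stop(sprintf("'%s' must be a finite numeric vector of length 3", what),
         call. = FALSE)
  as.numeric(p)
}

#' Signed dihedral (torsion) angle of four points
#'
#' Computes the torsion of `p1` about the `p2`->`p3` axis relative to `p4`,
#' following the IUPAC sign convention: looking from `p2` toward `p3`, a
#' clockwise rotation from the `p1` side to the `p4` side is positive.  The
#' cis arrangement (both outer points on the same side) gives 0 degrees,
#' trans gives +180 degrees; the returned value lies in (-180, +180], with
#' an exact half-turn mapped to +180 so that trans is a single value.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return The signed torsion in degrees, in (-180, 180].
#' @details Degenerate frames (coincident axis points, or either atom
#'   triple collinear within a cross-product norm of 1e-10) raise an error
#'   rather than returning an arbitrary angle.
#' @seealso [signed_improper()], [place_atom()]
#' @examples
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- .check_vec3(p1, "p1"); p2 <- .check_vec3(p2, "p2")
  p3 <- .check_vec3(p3, "p3"); p4 <- .check_vec3(p4, "p4")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  if (nb2 < 1e-8)
    stop("degenerate geometry: axis points p2 and p3 coincide", call. = FALSE)
  if (.vnorm(n1) < .COLLINEAR_TOL || .vnorm(n2) < .COLLINEAR_TOL)
    stop("degenerate geometry: collinear atom triple in dihedral frame",
         call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * (b2 / nb2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360  # map the boundary to +180
  ang
}

#' Signed improper dihedral over an ordered atom quadruple
#'
#' An improper dihedral is a torsion measured over four atoms that do not
#' form a linear bonded chain; here it is used with a chiral atom among the
#' four to discriminate enantiomers: the two mirror-image configurations of
#' a tetrahedral center give equal magnitudes of opposite sign.
#'
#' @param q A list of four numeric length-3 vectors, or a 4 x 3 numeric
#'   matrix of coordinates, in the template's order.
#' @return The signed improper angle in degrees, in (-180, 180].
#' @seealso [dihedral_angle()], [chiral_templates()]
#' @export
signed_improper <- function(q) {
  if (is.matrix(q)) {
    if (!all(dim(q) == c(4L, 3L)))
      stop("'q' must be a 4 x 3 matrix or a list of four length-3 vectors",
           call. = FALSE)
    q <- lapply(seq_len(4L), function(i) q[i, ])
  }
  if (!is.list(q) || length(q) != 4L)
    stop("'q' must be a 4 x 3 matrix or a list of four length-3 vectors",
         call. = FALSE)
  dihedral_angle(q[[1L]], q[[2L]], q[[3L]], q[[4L]])
}

#' Bond angle at a vertex
#'
#' @param p1,p2,p3 Numeric length-3 coordinate vectors; the angle is taken
#'   at `p2`.
#' @return The angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(p1, p2, p3) {
  p1 <- .check_vec3(p1, "p1"); p2 <- .check_vec3(p2, "p2")
  p3 <- .check_vec3(p3, "p3")
  u <- p1 - p2
  v <- p3 - p2
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu < 1e-8 || nv < 1e-8)
    stop("degenerate geometry: coincident points in angle", call. = FALSE)
  cosang <- max(-1, min(1, sum(u * v) / (nu * nv)))
  acos(cosang) * 180 / pi
}

#' Reflect a point through a center
#'
#' Point inversion: the image of `p` through `center` is `2 * center - p`.
#' This is the elementary move used to flip a peptide-bond oxygen/hydrogen
#' or a chiral center's hydrogen.
#'
#' @param p Numeric length-3 point to reflect.
#' @param center Numeric length-3 center of inversion.
#' @return The reflected point.
#' @export
point_reflect <- function(p, center) {
  p <- .check_vec3(p, "p")
  center <- .check_vec3(center, "center")
  2 * center - p
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' with `|d - c| = bond_length`, `angle(b, c, d) = bond_angle` and
#' `dihedral_angle(a, b, c, d) = torsion` (the natural-extension reference
#' frame construction used by internal-coordinate chain builders).
#'
#' @param a,b,c Numeric length-3 reference positions; `c` is the atom the
#'   new atom bonds to.
#' @param bond_length Distance `c`--`d` in Angstrom; must be positive.
#' @param bond_angle Angle at `c` in degrees, in (0, 180).
#' @param torsion Dihedral `a-b-c-d` in degrees.
#' @return The new position `d`.
#' @export
place_atom <- function(a, b, c, bond_length, bond_angle, torsion) {
  a <- .check_vec3(a, "a"); b <- .check_vec3(b, "b"); c <- .check_vec3(c, "c")
  if (!is.finite(bond_length) || bond_length <= 0)
    stop("'bond_length' must be positive", call. = FALSE)
  if (!is.finite(bond_angle) || bond_angle <= 0 || bond_angle >= 180)
    stop("'bond_angle' must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  ab <- b - a
  bc <- c - b
  nbc <- .vnorm(bc)
  if (nbc < 1e-8)
    stop("degenerate frame: b and c coincide", call. = FALSE)
  u <- bc / nbc
  n <- .cross(ab, u)
  if (.vnorm(n) < .COLLINEAR_TOL)
    stop("degenerate frame: a, b, c are collinear", call. = FALSE)
  n <- n / .vnorm(n)
  m <- .cross(n, u)
  th <- bond_angle * pi / 180
  ph <- torsion * pi / 180
  # local displacement: x along the extended b->c axis, y/z set by torsion
  d_loc <- bond_length * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_loc[1L] * u + d_loc[2L] * m + d_loc[3L] * n
}
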