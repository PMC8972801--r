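## Low-level vector geometry shared by the ring-measurement, puckering and
## regularizer code. All angles are in degrees, all lengths in Angstrom.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

## Wrap an angle in degrees to (-180, 180].
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

#' Dihedral angle of four points
#'
#' Computes the torsion (dihedral) angle defined by four points, using the
#' IUPAC sign convention: looking from \code{p2} towards \code{p3}, a
#' clockwise rotation of the far bond relative to the near bond is positive.
#' The result lies in (-180, 180] degrees and is antisymmetric under
#' reversing the order of the four points.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1))   # cis, 0
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))  # trans, 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10)
    stop("undefined torsion: three consecutive points are collinear")
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * .unit(b2))
  wrap_deg(.deg(atan2(y, x)))
}

## Angle p1-p2-p3 at the central point, degrees in [0, 180].
bond_angle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2)
  v <- .unit(p3 - p2)
  .deg(acos(max(-1, min(1, sum(u * v)))))
}

## Rotate point p about the axis through origin o with unit direction u by
## `ang` degrees (right-hand rule). Rodrigues formula.
rotate_about_axis <- function(p, o, u, ang) {
  u <- .unit(u)
  v <- p - o
  a <- .rad(ang)
  o + v * cos(a) + .cross(u, v) * sin(a) + u * sum(u * v) * (1 - cos(a))
}

## Fetch named atom rows out of a coordinate matrix, with a clear error.
.coords_of <- function(coords, names) {
  missing <- setdiff(names, rownames(coords))
  if (length(missing))
    stop("missing atom(s) in coordinates: ", paste(missing, collapse = ", "))
  coords[names, , drop = FALSE]
}

#' Endocyclic torsions of a six-membered ring
#'
#' Measures the six ring torsions in ring order. Torsion \code{k} is about
#' the bond between ring positions \code{k} and \code{k+1} (cyclic), using
#' the four cyclically consecutive ring atoms
#' \code{r[k-1], r[k], r[k+1], r[k+2]}. With the ring ordered oxygen-first
#' and traversed through the anomeric carbon, torsion 2 of an aldopyranose
#' is the O5-C1-C2-C3 torsion.
#'
#' @param coords coordinate matrix with atom-name rownames (see
#'   \code{\link{as_monomer_coords}}).
#' @param ring character vector of six ring atom names in ring order
#'   (oxygen first), as from \code{\link{detect_ring}}.
#' @return numeric vector of six torsions (degrees), named by the four atoms.
#' @export
ring_torsions <- function(coords, ring) {
  stopifnot(length(ring) == 6)
  xyz <- .coords_of(coords, ring)
  idx <- function(k) ((k - 1) %% 6) + 1
  out <- numeric(6)
  nm <- character(6)
  for (k in 1:6) {
    quad <- c(idx(k - 1), idx(k), idx(k + 1), idx(k + 2))
    out[k] <- dihedral_angle(xyz[quad[1], ], xyz[quad[2], ],
                             xyz[quad[3], ], xyz[quad[4], ])
    nm[k] <- paste(ring[quad], collapse = "-")
  }
  names(out) <- nm
  out
}
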