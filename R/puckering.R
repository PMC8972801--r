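## Cremer-Pople puckering analysis for six-membered rings: forward transform
## (coordinates -> Q, theta, phi), inverse transform (build a ring at a
## target pucker) and classification onto the 38 canonical pyranose
## conformers. Atom index j = 0 is always the ring oxygen and the traversal
## runs towards the anomeric carbon; with that convention theta = 0 is the
## 4C1 chair of a D-aldopyranose and theta = 180 the 1C4 chair.

#' Cremer-Pople puckering coordinates from ring coordinates
#'
#' Applies the Cremer-Pople prescription for a six-membered ring: the ring
#' centre is the geometric mean of the six atoms; the mean plane is fixed by
#' the two first-order trigonometric moment conditions; \code{z} are the
#' out-of-plane displacements; the second-order Fourier sums give
#' \code{q2, phi} and the alternating sum gives \code{q3}. The total
#' amplitude is \code{Q = sqrt(q2^2 + q3^2)} and
#' \code{theta = atan2(q2, q3)} in [0, 180].
#'
#' Rings with \code{Q} below \code{planarity_q} are reported as planar:
#' \code{theta} and \code{phi} are set to \code{NA} (flagged, not an error).
#'
#' @param coords coordinates containing (at least) the six ring atoms.
#' @param ring six ring atom names in ring order, oxygen first (see
#'   \code{\link{detect_ring}}); alternatively \code{coords} may be a plain
#'   6 x 3 matrix in ring order with \code{ring} omitted.
#' @param planarity_q amplitude (Angstrom) below which the ring is treated
#'   as planar; default 0.1.
#' @return object of class \code{pucker_coords}: list with \code{Q},
#'   \code{theta}, \code{phi} (degrees), \code{q2}, \code{q3}, \code{z}
#'   (named displacements), \code{planar} flag, \code{ring} and the mean
#'   plane \code{normal} and \code{centre}.
#' @export
cremer_pople <- function(coords, ring = NULL, planarity_q = 0.1) {
  if (is.null(ring)) {
    stopifnot(nrow(coords) == 6)
    xyz <- as.matrix(coords)[, 1:3, drop = FALSE]
    ring <- rownames(coords)
    if (is.null(ring)) ring <- paste0("A", 0:5)
  } else {
    xyz <- unclass(.coords_of(coords, ring))[, 1:3, drop = FALSE]
  }
  j <- 0:5
  centre <- colMeans(xyz)
  rel <- sweep(xyz, 2, centre)
  Rp <- colSums(rel * sin(2 * pi * j / 6))
  Rpp <- colSums(rel * cos(2 * pi * j / 6))
  nvec <- .cross(Rp, Rpp)
  if (.vnorm(nvec) < 1e-10)
    stop("degenerate ring: zero-area mean-plane projection")
  nvec <- .unit(nvec)
  z <- as.numeric(rel %*% nvec)
  q2c <- sqrt(1 / 3) * sum(z * cos(2 * pi * 2 * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(2 * pi * 2 * j / 6))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  planar <- Q < planarity_q
  theta <- if (planar) NA_real_ else .deg(atan2(q2, q3))
  phi <- if (planar || q2 < 1e-12) {
    if (planar) NA_real_ else 0
  } else {
    (.deg(atan2(q2s, q2c))) %% 360
  }
  names(z) <- ring
  structure(list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3,
                 z = z, planar = planar, ring = ring,
                 normal = nvec, centre = centre),
            class = "pucker_coords")
}

#' @export
print.pucker_coords <- function(x, ...) {
  if (x$planar) {
    cat(sprintf("pucker_coords: planar ring (Q = %.3f A)\n", x$Q))
  } else {
    cat(sprintf("pucker_coords: Q = %.3f A, theta = %.2f deg, phi = %.2f deg\n",
                x$Q, x$theta, x$phi))
  }
  invisible(x)
}

#' Build a six-membered ring at a target pucker (inverse transform)
#'
#' Places six atoms on a regular hexagon of the given radius in the xy
#' plane (vertex \code{j} at angle \code{-60j} degrees so that the
#' Cremer-Pople mean-plane normal is +z) and adds the out-of-plane
#' displacements \code{z_j = sqrt(1/3) q2 cos(phi + 120 j) +
#' sqrt(1/6) q3 (-1)^j} with \code{q2 = Q sin(theta)},
#' \code{q3 = Q cos(theta)}. The round trip through
#' \code{\link{cremer_pople}} recovers (Q, theta, phi) to high precision.
#'
#' @param Q total puckering amplitude (Angstrom, >= 0).
#' @param theta polar pucker angle, degrees in [0, 180].
#' @param phi pseudorotation phase, degrees.
#' @param radius hexagon radius (Angstrom); 1.45 approximates pyranose
#'   bond lengths.
#' @param names atom names for the six ring positions (oxygen first).
#' @return \code{monomer_coords} with six atoms in ring order.
#' @export
build_ring <- function(Q, theta, phi = 0, radius = 1.45,
                       names = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  stopifnot(Q >= 0, radius > 0, length(names) == 6)
  j <- 0:5
  q2 <- Q * sin(.rad(theta))
  q3 <- Q * cos(.rad(theta))
  z <- sqrt(1 / 3) * q2 * cos(.rad(phi) + 2 * pi * 2 * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  ang <- -2 * pi * j / 6
  xyz <- cbind(x = radius * cos(ang), y = radius * sin(ang), z = z)
  rownames(xyz) <- names
  as_monomer_coords(xyz)
}

## ---- canonical conformer table ------------------------------------------

## The 38 canonical pyranose conformers with their Cremer-Pople (theta, phi)
## under this package's convention (ring oxygen at j = 0, traversal towards
## the anomeric carbon, phi = 0 at the O,3B boat). Chairs sit at the poles;
## boats at theta = 90 with phi at multiples of 60; skew-boats at theta = 90,
## phi = 30 + 60k; envelopes at theta = 54.74/125.26 (phi = 60k) and
## half-chairs at theta = 50.77/129.23 (phi = 30 + 60k), the exact positions
## of the ideal one-atom-out and two-atom-out displacement patterns under
## the Cremer-Pople mode decomposition.
.theta_E <- 54.7356103172453   # atan(sqrt(2)) in degrees
.theta_H <- 50.7684795164077   # atan(sqrt(3)/sqrt(2) * sqrt(... )): atan2(1, sqrt(2/3))

#' Canonical pyranose conformer table
#'
#' Returns the table of the 38 canonical six-ring conformers (2 chairs,
#' 6 boats, 6 skew-boats, 12 envelopes, 12 half-chairs) with their
#' canonical Cremer-Pople \code{(theta, phi)} and family.
#'
#' @return data frame with columns \code{name}, \code{family}
#'   (\code{chair}, \code{boat}, \code{skew-boat}, \code{envelope},
#'   \code{half-chair}), \code{theta}, \code{phi}.
#' @export
.conformer_cache <- new.env(parent = emptyenv())

conformer_table <- function() {
  if (!is.null(.conformer_cache$tab)) return(.conformer_cache$tab)
  tab <- rbind(
    data.frame(name = c("4C1", "1C4"), family = "chair",
               theta = c(0, 180), phi = c(0, 0)),
    data.frame(name = c("O,3B", "B1,4", "2,5B", "B3,O", "1,4B", "B2,5"),
               family = "boat", theta = 90, phi = c(0, 60, 120, 180, 240, 300)),
    data.frame(name = c("3S1", "5S1", "2SO", "1S3", "1S5", "OS2"),
               family = "skew-boat", theta = 90,
               phi = c(30, 90, 150, 210, 270, 330)),
    ## envelopes: atom k displaced up (kE, north for even k) or down (Ek)
    data.frame(name = c("OE", "E1", "2E", "E3", "4E", "E5"),
               family = "envelope", theta = .theta_E,
               phi = c(0, 60, 120, 180, 240, 300)),
    data.frame(name = c("3E", "E4", "5E", "EO", "1E", "E2"),
               family = "envelope", theta = 180 - .theta_E,
               phi = c(0, 60, 120, 180, 240, 300)),
    ## half-chairs: adjacent atoms j up / k down
    data.frame(name = c("OH1", "2H1", "2H3", "4H3", "4H5", "OH5"),
               family = "half-chair", theta = .theta_H,
               phi = c(30, 90, 150, 210, 270, 330)),
    data.frame(name = c("3H4", "5H4", "5HO", "1HO", "1H2", "3H2"),
               family = "half-chair", theta = 180 - .theta_H,
               phi = c(30, 90, 150, 210, 270, 330))
  )
  rownames(tab) <- NULL
  .conformer_cache$tab <- tab
  tab
}

## Arc distance (degrees) between two points on the (theta, phi) sphere.
sphere_arc <- function(theta1, phi1, theta2, phi2) {
  t1 <- .rad(theta1); t2 <- .rad(theta2)
  dp <- .rad(phi1 - phi2)
  c0 <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dp)
  .deg(acos(pmax(-1, pmin(1, c0))))
}

#' Classify a pucker onto the canonical conformers
#'
#' Finds the nearest of the 38 canonical conformers by spherical arc
#' distance on the (theta, phi) sphere. Ties are broken towards the
#' lower-energy family (chair, then boat/skew-boat, then
#' envelope/half-chair) and then lexicographically by name. A planar ring
#' receives the pseudo-label \code{"planar"}.
#'
#' @param pucker a \code{pucker_coords} object, or a list with
#'   \code{theta} and \code{phi} in degrees.
#' @return object of class \code{conformer_label}: list with \code{name},
#'   \code{family}, canonical \code{theta}, \code{phi} and the arc
#'   \code{distance} (degrees) from the input.
#' @export
classify_conformer <- function(pucker) {
  if (isTRUE(pucker$planar) || is.na(pucker$theta))
    return(structure(list(name = "planar", family = "planar",
                          theta = NA_real_, phi = NA_real_,
                          distance = NA_real_), class = "conformer_label"))
  tab <- conformer_table()
  d <- sphere_arc(pucker$theta, pucker$phi, tab$theta, tab$phi)
  fam_rank <- match(tab$family,
                    c("chair", "boat", "skew-boat", "envelope", "half-chair"))
  ord <- order(round(d, 9), fam_rank, tab$name)
  k <- ord[1]
  structure(list(name = tab$name[k], family = tab$family[k],
                 theta = tab$theta[k], phi = tab$phi[k],
                 distance = d[k]), class = "conformer_label")
}

#' @export
print.conformer_label <- function(x, ...) {
  if (x$name == "planar") cat("conformer: planar ring\n")
  else cat(sprintf("conformer: %s (%s), %.1f deg from canonical point\n",
                   x$name, x$family, x$distance))
  invisible(x)
}

#' Is a conformer a high-energy (unexpected) one?
#'
#' A sugar is flagged high-energy when its classified conformer differs
#' from the expected lowest-energy conformer for that sugar (4C1 for
#' D-pyranoses, 1C4 for L-pyranoses, unless overridden).
#'
#' @param label observed conformer (\code{conformer_label} or name string).
#' @param expected expected conformer (\code{conformer_label} or name).
#' @return logical flag.
#' @export
is_high_energy <- function(label, expected) {
  nm <- if (inherits(label, "conformer_label")) label$name else as.character(label)
  ex <- if (inherits(expected, "conformer_label")) expected$name else as.character(expected)
  !identical(nm, ex)
}
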