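## Synthetic fixture generation: idealized sugar monomers with
## substituents, matching restraint dictionaries (AceDRG-style generic
## torsions), legacy-style dictionaries with uniform sigma 20, and ring
## distortion between puckers. Substituent placement uses idealized
## tetrahedral geometry (1.52 A C-C, 1.43 A C-O, 109.47 deg angles): enough
## for validation logic, with no claim to database-derived targets. These
## are synthetic stand-ins, not the released CCP4-ML entries.

## stereo configuration map: which hydroxyls are axial in the D-series 4C1
## reference frame (gluco = none; manno = O2; galacto = O4)
.axial_map <- list(
  NAG = character(0), GLC = character(0), BGC = character(0),
  BOG = character(0), MAN = "O2", BMA = "O2", GAL = "O4", GLA = "O4",
  FUL = "O4", FUC = "O4")

## The two tetrahedral substituent unit vectors at ring atom `i` given its
## ring neighbours; returns list(axial, equatorial) classified against the
## ring normal.
.substituent_slots <- function(xyz, i_prev, i, i_next, normal) {
  u1 <- .unit(xyz[i_prev, ] - xyz[i, ])
  u2 <- .unit(xyz[i_next, ] - xyz[i, ])
  b <- .unit(-(u1 + u2))
  nv <- .unit(.cross(u1, u2))
  a <- cos(.rad(109.47)) / sum(b * u1)
  cc <- sqrt(max(0, 1 - a^2))
  s1 <- a * b + cc * nv
  s2 <- a * b - cc * nv
  if (abs(sum(s1 * normal)) >= abs(sum(s2 * normal)))
    list(axial = s1, equatorial = s2)
  else list(axial = s2, equatorial = s1)
}

#' Generate a synthetic sugar monomer and its dictionary
#'
#' Builds an idealized aldopyranose: the ring at the requested conformer's
#' canonical pucker (amplitude 0.55 A), exocyclic substituents (O1..O4, C6,
#' O6) placed axially or equatorially according to the series, anomer and
#' the component's stereo configuration, plus a matching restraint
#' dictionary with measured bonds/angles, chirality signs computed from the
#' built coordinates, and AceDRG-style generic torsions (sigma 10, ring
#' torsions at the generic 60 degrees) ready for
#' \code{\link{patch_dictionary}}.
#'
#' The sugar is first built in its series' reference chair (4C1 for D,
#' obtained for L by mirror inversion, giving 1C4) and then moved to the
#' requested conformer with \code{\link{distort_ring}}, which preserves the
#' stereochemistry.
#'
#' @param series \code{"D"} or \code{"L"}.
#' @param conformer canonical conformer name (see
#'   \code{\link{conformer_table}}); typically \code{"4C1"} or
#'   \code{"1C4"}.
#' @param anomer \code{"alpha"} or \code{"beta"}.
#' @param comp_id component code; known codes select the matching stereo
#'   configuration, unknown codes default to gluco.
#' @param Q ring puckering amplitude (Angstrom); default 0.55.
#' @return list with \code{coords} (\code{monomer_coords}) and
#'   \code{dictionary} (\code{restraint_dictionary} whose model
#'   coordinates are the built conformer).
#' @export
make_sugar <- function(series = c("D", "L"), conformer = NULL,
                       anomer = c("beta", "alpha"), comp_id = "GLC",
                       Q = 0.55) {
  series <- match.arg(series)
  anomer <- match.arg(anomer)
  if (is.null(conformer)) conformer <- if (series == "D") "4C1" else "1C4"
  tab <- conformer_table()
  if (!conformer %in% tab$name) stop("unknown conformer: ", conformer)

  ## reference chair in the D frame
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  ring <- build_ring(Q, theta = 0, phi = 0, radius = 1.45, names = ring_names)
  xyz <- unclass(ring)[, 1:3, drop = FALSE]
  cp <- cremer_pople(ring)
  N <- cp$normal

  axial_subs <- .axial_map[[comp_id]]
  if (is.null(axial_subs)) axial_subs <- character(0)
  place <- list(
    O1 = list(on = "C1", len = 1.43,
              slot = if (anomer == "alpha") "axial" else "equatorial"),
    O2 = list(on = "C2", len = 1.43,
              slot = if ("O2" %in% axial_subs) "axial" else "equatorial"),
    O3 = list(on = "C3", len = 1.43,
              slot = if ("O3" %in% axial_subs) "axial" else "equatorial"),
    O4 = list(on = "C4", len = 1.43,
              slot = if ("O4" %in% axial_subs) "axial" else "equatorial"),
    C6 = list(on = "C5", len = 1.52, slot = "equatorial"))

  out <- xyz
  bonds <- data.frame(atom1 = ring_names,
                      atom2 = ring_names[c(2:6, 1)],
                      stringsAsFactors = FALSE)
  for (nm in names(place)) {
    p <- place[[nm]]
    i <- match(p$on, ring_names)
    slots <- .substituent_slots(xyz, ((i - 2) %% 6) + 1, i, (i %% 6) + 1, N)
    pos <- xyz[i, ] + p$len * slots[[p$slot]]
    out <- rbind(out, pos)
    rownames(out)[nrow(out)] <- nm
    bonds <- rbind(bonds, data.frame(atom1 = p$on, atom2 = nm))
  }
  ## O6 on C6, staggered away from the ring
  u <- .unit(out["C6", ] - out["C5", ])
  perp <- .unit(N - sum(N * u) * u)
  o6 <- out["C6", ] + 1.43 * (u / 3 + perp * sqrt(1 - 1 / 9))
  out <- rbind(out, O6 = o6)
  bonds <- rbind(bonds, data.frame(atom1 = "C6", atom2 = "O6"))

  if (series == "L") out[, 1] <- -out[, 1]   # mirror: 4C1 -> 1C4, D -> L
  coords <- as_monomer_coords(out)

  ## move to the requested conformer
  ref_chair <- if (series == "D") "4C1" else "1C4"
  if (conformer != ref_chair) {
    k <- match(conformer, tab$name)
    coords <- distort_ring(coords, theta = tab$theta[k], phi = tab$phi[k],
                           fraction = 1, ring = ring_names)
  }

  atoms <- data.frame(name = rownames(coords),
                      element = substr(rownames(coords), 1, 1),
                      charge = 0, stringsAsFactors = FALSE)
  m <- unclass(coords)[, 1:3, drop = FALSE]
  bonds$order <- "single"
  bonds$value <- vapply(seq_len(nrow(bonds)), function(i)
    .vnorm(m[bonds$atom1[i], ] - m[bonds$atom2[i], ]), numeric(1))
  bonds$sigma <- 0.015
  bonds$value <- round(bonds$value, 3)

  ## angles: every neighbour pair around every atom
  adj <- lapply(setNames(nm = atoms$name), function(a)
    c(bonds$atom2[bonds$atom1 == a], bonds$atom1[bonds$atom2 == a]))
  ang <- list()
  for (b in atoms$name) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    for (i in seq_len(length(nb) - 1)) for (j in seq(i + 1, length(nb))) {
      ang[[length(ang) + 1]] <- data.frame(
        atom1 = nb[i], atom2 = b, atom3 = nb[j],
        value = round(bond_angle(m[nb[i], ], m[b, ], m[nb[j], ]), 3),
        sigma = 2.0, stringsAsFactors = FALSE)
    }
  }
  angles <- do.call(rbind, ang)

  ## generic AceDRG-style torsions: one per central bond with flanking
  ## heavy atoms; ring bonds get the generic 60 deg, period 3
  ring_set <- ring_names
  tors <- list()
  k <- 0
  for (i in seq_len(nrow(bonds))) {
    b2 <- bonds$atom1[i]; b3 <- bonds$atom2[i]
    n2 <- setdiff(adj[[b2]], b3); n3 <- setdiff(adj[[b3]], b2)
    if (!length(n2) || !length(n3)) next
    k <- k + 1
    in_ring <- b2 %in% ring_set && b3 %in% ring_set
    if (in_ring) {   # generic ring torsion runs along the ring
      n2 <- c(intersect(n2, ring_set), n2)
      n3 <- c(intersect(n3, ring_set), n3)
    }
    tors[[k]] <- data.frame(
      id = paste0("tor_", k), atom1 = n2[1], atom2 = b2, atom3 = b3,
      atom4 = n3[1],
      value = if (in_ring) 60 else 180, sigma = 10, period = 3L,
      stringsAsFactors = FALSE)
  }
  torsions <- do.call(rbind, tors)

  ## chiral centres: ring carbons with three heavy neighbours, signs
  ## measured from the built coordinates
  chir <- list()
  for (cc in c("C1", "C2", "C3", "C4", "C5")) {
    nb <- sort(adj[[cc]])
    if (length(nb) < 3) next
    nb <- nb[1:3]
    v1 <- m[nb[1], ] - m[cc, ]; v2 <- m[nb[2], ] - m[cc, ]
    v3 <- m[nb[3], ] - m[cc, ]
    vol <- sum(.cross(v1, v2) * v3)
    chir[[length(chir) + 1]] <- data.frame(
      id = paste0("chir_", length(chir) + 1), centre = cc,
      atom1 = nb[1], atom2 = nb[2], atom3 = nb[3],
      sign = if (vol > 0) "positive" else "negative",
      stringsAsFactors = FALSE)
  }
  chiralities <- do.call(rbind, chir)

  dict <- restraint_dictionary(
    comp_id = comp_id,
    comp_name = paste0("synthetic ", series, "-pyranose ", comp_id),
    comp_type = "pyranose",
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    chiralities = chiralities,
    model_coords = as_monomer_coords(round(m, 3)))
  list(coords = coords, dictionary = dict)
}

## Best-fit proper rotation + translation mapping points A onto B (Kabsch).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

#' Distort a pyranose ring towards a target pucker
#'
#' Interpolates the Cremer-Pople displacement field from the current
#' pucker to the target \code{(theta, phi)} (amplitude kept) by the given
#' fraction, rebuilding the ring in its own mean-plane frame. Substituent
#' atoms stay rigidly attached to the local frame of their ring atom, so
#' chirality is preserved for any fraction.
#'
#' @param coords \code{monomer_coords} containing a pyranose ring.
#' @param theta,phi target pucker (degrees).
#' @param fraction interpolation fraction in [0, 1]; 0 returns the input.
#' @param ring optional ring atom names; inferred from distance-based
#'   connectivity when omitted.
#' @return distorted \code{monomer_coords} (same atoms, same order).
#' @export
distort_ring <- function(coords, theta, phi, fraction = 1, ring = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(coords)
  if (is.null(ring)) ring <- detect_ring_coords(coords)
  cp <- cremer_pople(coords, ring)
  N <- cp$normal
  m <- unclass(coords)[, 1:3, drop = FALSE]

  v_cur <- c(cp$q2 * cos(.rad(cp$phi %||% 0)), cp$q2 * sin(.rad(cp$phi %||% 0)),
             cp$q3)
  v_tgt <- c(cp$Q * sin(.rad(theta)) * cos(.rad(phi)),
             cp$Q * sin(.rad(theta)) * sin(.rad(phi)),
             cp$Q * cos(.rad(theta)))
  v <- (1 - fraction) * v_cur + fraction * v_tgt
  q2 <- sqrt(v[1]^2 + v[2]^2)
  phi2 <- if (q2 < 1e-12) 0 else atan2(v[2], v[1])
  q3 <- v[3]
  j <- 0:5
  z_new <- sqrt(1 / 3) * q2 * cos(phi2 + 2 * pi * 2 * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j

  old_ring <- m[ring, , drop = FALSE]
  inplane <- old_ring - outer(cp$z, N)
  new_ring <- inplane + outer(z_new, N)

  ## attach exocyclic subtrees to their ring atom and move them rigidly
  bonds <- infer_bonds(coords)
  adj <- lapply(setNames(nm = rownames(m)), function(a)
    c(bonds$atom2[bonds$atom1 == a], bonds$atom1[bonds$atom2 == a]))
  owner <- setNames(rep(NA_character_, nrow(m)), rownames(m))
  owner[ring] <- ring
  frontier <- ring
  while (length(frontier)) {
    nxt <- character(0)
    for (a in frontier) for (nb in adj[[a]]) {
      if (is.na(owner[nb])) {
        owner[nb] <- if (a %in% ring) a else owner[a]
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }

  out <- m
  out[ring, ] <- new_ring
  for (i in seq_along(ring)) {
    sub_atoms <- setdiff(names(owner)[!is.na(owner) & owner == ring[i]], ring)
    if (!length(sub_atoms)) next
    prev <- ring[((i - 2) %% 6) + 1]; nxt <- ring[(i %% 6) + 1]
    A <- m[c(prev, ring[i], nxt), , drop = FALSE]
    B <- new_ring[c(((i - 2) %% 6) + 1, i, (i %% 6) + 1), , drop = FALSE]
    tr <- .kabsch(A, B)
    out[sub_atoms, ] <- sweep(m[sub_atoms, , drop = FALSE] %*% t(tr$R), 2,
                              -tr$t)
  }
  as_monomer_coords(out)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Convert a dictionary to legacy style
#'
#' Emulates the LIBCHECK-era CCP4-ML entries: every torsion sigma becomes
#' the uniform 20.0 degrees, the ring/tors naming is collapsed to a single
#' undifferentiated \code{var_<k>} scheme, and periodicities 2/3/6 are
#' assigned heuristically (3 for saturated sp3 quadruples, 2 when the
#' central bond touches a non-ring oxygen, 6 as fallback for terminal
#' quadruples).
#'
#' @param d \code{\link{restraint_dictionary}}.
#' @return legacy-style \code{restraint_dictionary}.
#' @export
make_legacy_dictionary <- function(d) {
  t <- d$torsions
  if (nrow(t)) {
    elem <- setNames(toupper(substr(d$atoms$name, 1, 1)), d$atoms$name)
    per <- vapply(seq_len(nrow(t)), function(i) {
      central <- c(t$atom2[i], t$atom3[i])
      if (any(elem[central] == "O")) 2L else 3L
    }, integer(1))
    term <- t$atom1 == t$atom4
    per[term] <- 6L
    d$torsions <- data.frame(id = paste0("var_", seq_len(nrow(t))),
                             atom1 = t$atom1, atom2 = t$atom2,
                             atom3 = t$atom3, atom4 = t$atom4,
                             value = t$value, sigma = 20.0, period = per,
                             stringsAsFactors = FALSE)
  }
  check_dictionary(d)
  d
}

#' Bare-ring fixture: dictionary and chair coordinates
#'
#' Builds a six-atom pyranose ring (no substituents) at the 4C1 chair with
#' measured bond and angle restraints, ready for
#' \code{\link{patch_dictionary}} and the regularizer demos.
#'
#' @param Q puckering amplitude (Angstrom); default 0.55.
#' @param radius hexagon radius passed to \code{\link{build_ring}}.
#' @return list with \code{coords} (chair \code{monomer_coords}) and
#'   \code{dictionary}.
#' @export
make_ring_fixture <- function(Q = 0.55, radius = 1.45) {
  chair <- build_ring(Q, theta = 0, phi = 0, radius = radius)
  nm <- rownames(chair)
  m <- unclass(chair)[, 1:3, drop = FALSE]
  bonds <- data.frame(atom1 = nm, atom2 = nm[c(2:6, 1)], order = "single",
                      value = NA_real_, sigma = 0.015,
                      stringsAsFactors = FALSE)
  bonds$value <- round(vapply(1:6, function(i)
    .vnorm(m[bonds$atom1[i], ] - m[bonds$atom2[i], ]), numeric(1)), 3)
  angles <- data.frame(atom1 = nm[c(6, 1:5)], atom2 = nm,
                       atom3 = nm[c(2:6, 1)], value = NA_real_, sigma = 2.0,
                       stringsAsFactors = FALSE)
  angles$value <- round(vapply(1:6, function(i)
    bond_angle(m[angles$atom1[i], ], m[angles$atom2[i], ],
               m[angles$atom3[i], ]), numeric(1)), 3)
  atoms <- data.frame(name = nm, element = substr(nm, 1, 1), charge = 0,
                      stringsAsFactors = FALSE)
  d <- restraint_dictionary("RNG", comp_name = "synthetic bare pyranose ring",
                            atoms = atoms, bonds = bonds, angles = angles,
                            model_coords = as_monomer_coords(round(m, 3)))
  list(coords = chair, dictionary = d)
}
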