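## Toy restrained geometry regularizer. This is explicitly NOT a
## crystallographic refinement engine: it exists to make the behaviour of
## unimodal ring torsion restraints observable at desk scale - a distorted
## ring pulled back to the minimal-energy chair by tight ring torsions,
## unless a strongly weighted density term holds a high-energy conformer,
## mirroring how refinement down-weights torsion restraints against strong
## observations.

#' Build restraint targets from a dictionary
#'
#' Flattens a dictionary's bond, angle and torsion restraints into the
#' target table used by \code{\link{restraint_energy}}.
#'
#' @param d \code{\link{restraint_dictionary}}.
#' @param kinds subset of \code{c("bond", "angle", "torsion")}.
#' @param ring_only_torsions if \code{TRUE}, keep only \code{ring_}
#'   torsions; if \code{FALSE} keep all; \code{NA} drops all torsions.
#' @return data frame with columns \code{kind, atom1..atom4, target,
#'   sigma, period}.
#' @export
restraints_from_dictionary <- function(d, kinds = c("bond", "angle", "torsion"),
                                       ring_only_torsions = FALSE) {
  out <- list()
  if ("bond" %in% kinds && nrow(d$bonds))
    out$bond <- data.frame(kind = "bond", atom1 = d$bonds$atom1,
                           atom2 = d$bonds$atom2, atom3 = NA, atom4 = NA,
                           target = d$bonds$value, sigma = d$bonds$sigma,
                           period = 1L, stringsAsFactors = FALSE)
  if ("angle" %in% kinds && nrow(d$angles))
    out$angle <- data.frame(kind = "angle", atom1 = d$angles$atom1,
                            atom2 = d$angles$atom2, atom3 = d$angles$atom3,
                            atom4 = NA, target = d$angles$value,
                            sigma = d$angles$sigma, period = 1L,
                            stringsAsFactors = FALSE)
  if ("torsion" %in% kinds && nrow(d$torsions)) {
    t <- d$torsions
    if (isTRUE(ring_only_torsions)) t <- t[grepl("^ring_", t$id), , drop = FALSE]
    if (nrow(t))
      out$torsion <- data.frame(kind = "torsion", atom1 = t$atom1,
                                atom2 = t$atom2, atom3 = t$atom3,
                                atom4 = t$atom4, target = t$value,
                                sigma = t$sigma, period = as.integer(t$period),
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Periodic torsion residual: distance (degrees) to the nearest of the
## period-p symmetry-equivalent targets.
.periodic_residual <- function(measured, target, period) {
  p <- max(1L, as.integer(period))
  span <- 360 / p
  d <- (measured - target) %% span
  ifelse(d > span / 2, d - span, d)
}

## Trilinear interpolation of a density grid at a point, with gradient.
.trilinear <- function(g, p) {
  d <- dim(g$values)
  f <- (p - g$origin) / g$spacing
  i0 <- floor(f)
  if (any(i0 < 0) || any(i0 > d - 2))
    return(list(value = 0, grad = c(0, 0, 0)))   # outside: flat zero tail
  t <- f - i0
  i <- i0 + 1L
  v <- g$values
  c000 <- v[i[1], i[2], i[3]];     c100 <- v[i[1] + 1, i[2], i[3]]
  c010 <- v[i[1], i[2] + 1, i[3]]; c110 <- v[i[1] + 1, i[2] + 1, i[3]]
  c001 <- v[i[1], i[2], i[3] + 1]; c101 <- v[i[1] + 1, i[2], i[3] + 1]
  c011 <- v[i[1], i[2] + 1, i[3] + 1]; c111 <- v[i[1] + 1, i[2] + 1, i[3] + 1]
  tx <- t[1]; ty <- t[2]; tz <- t[3]
  c00 <- c000 * (1 - tx) + c100 * tx
  c10 <- c010 * (1 - tx) + c110 * tx
  c01 <- c001 * (1 - tx) + c101 * tx
  c11 <- c011 * (1 - tx) + c111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  val <- c0 * (1 - tz) + c1 * tz
  dx <- ((c100 - c000) * (1 - ty) + (c110 - c010) * ty) * (1 - tz) +
    ((c101 - c001) * (1 - ty) + (c111 - c011) * ty) * tz
  dy <- ((c010 - c000) * (1 - tx) + (c110 - c100) * tx) * (1 - tz) +
    ((c011 - c001) * (1 - tx) + (c111 - c101) * tx) * tz
  dz <- (c001 * (1 - tx) + c101 * tx - c000 * (1 - tx) - c100 * tx) * (1 - ty) +
    (c011 * (1 - tx) + c111 * tx - c010 * (1 - tx) - c110 * tx) * ty
  list(value = val, grad = c(dx, dy, dz) / g$spacing)
}

#' Restraint energy and gradient
#'
#' Evaluates \code{sum(((measured - target)/sigma)^2)} over bond, angle and
#' torsion restraints (torsion residuals wrapped to the nearest of the
#' period-p equivalent targets), minus \code{weight} times the interpolated
#' density at the atom positions when a density term is given. The gradient
#' is analytic and consistent with the scalar.
#'
#' @param coords \code{monomer_coords}.
#' @param restraints restraint table from
#'   \code{\link{restraints_from_dictionary}}.
#' @param density optional \code{density_grid}.
#' @param weight density weight (>= 0); the data-vs-geometry balance knob.
#' @return list with \code{value} and \code{gradient} (n x 3 matrix in the
#'   row order of \code{coords}).
#' @export
restraint_energy <- function(coords, restraints, density = NULL, weight = 0) {
  xyz <- unclass(coords)[, 1:3, drop = FALSE]
  nm <- rownames(coords)
  grad <- matrix(0, nrow(xyz), 3, dimnames = list(nm, NULL))
  E <- 0
  for (i in seq_len(nrow(restraints))) {
    r <- restraints[i, ]
    if (r$kind == "bond") {
      a <- match(r$atom1, nm); b <- match(r$atom2, nm)
      v <- xyz[a, ] - xyz[b, ]
      len <- .vnorm(v)
      res <- (len - r$target) / r$sigma
      E <- E + res^2
      gv <- 2 * res / r$sigma * v / len
      grad[a, ] <- grad[a, ] + gv
      grad[b, ] <- grad[b, ] - gv
    } else if (r$kind == "angle") {
      a <- match(r$atom1, nm); b <- match(r$atom2, nm); c3 <- match(r$atom3, nm)
      u <- xyz[a, ] - xyz[b, ]
      v <- xyz[c3, ] - xyz[b, ]
      lu <- .vnorm(u); lv <- .vnorm(v)
      uh <- u / lu; vh <- v / lv
      cth <- max(-1, min(1, sum(uh * vh)))
      th <- .deg(acos(cth))
      sth <- sqrt(max(1e-12, 1 - cth^2))
      res <- (th - r$target) / r$sigma
      E <- E + res^2
      pref <- 2 * res / r$sigma * (-180 / pi) / sth
      da <- pref * (vh - cth * uh) / lu
      dc <- pref * (uh - cth * vh) / lv
      grad[a, ] <- grad[a, ] + da
      grad[c3, ] <- grad[c3, ] + dc
      grad[b, ] <- grad[b, ] - da - dc
    } else if (r$kind == "torsion") {
      ia <- match(c(r$atom1, r$atom2, r$atom3, r$atom4), nm)
      p <- xyz[ia, , drop = FALSE]
      phi <- tryCatch(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                      error = function(e) NA_real_)
      if (is.na(phi)) {
        warning("skipping undefined torsion ", r$atom1, "-", r$atom2, "-",
                r$atom3, "-", r$atom4)
        next
      }
      res <- .periodic_residual(phi, r$target, r$period) / r$sigma
      E <- E + res^2
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
      lb2 <- .vnorm(b2)
      G1 <- lb2 / sum(n1 * n1) * n1
      G4 <- lb2 / sum(n2 * n2) * n2
      c12 <- sum(b1 * b2) / lb2^2
      c32 <- sum(b3 * b2) / lb2^2
      g1 <- -G1
      g2 <- (1 + c12) * G1 + c32 * G4
      g3 <- -c12 * G1 - (1 + c32) * G4
      g4 <- G4
      pref <- 2 * res / r$sigma * (180 / pi)
      grad[ia[1], ] <- grad[ia[1], ] + pref * g1
      grad[ia[2], ] <- grad[ia[2], ] + pref * g2
      grad[ia[3], ] <- grad[ia[3], ] + pref * g3
      grad[ia[4], ] <- grad[ia[4], ] + pref * g4
    } else stop("unknown restraint kind: ", r$kind)
  }
  if (!is.null(density) && weight > 0) {
    for (a in seq_len(nrow(xyz))) {
      ti <- .trilinear(density, xyz[a, ])
      E <- E - weight * ti$value
      grad[a, ] <- grad[a, ] - weight * ti$grad
    }
  }
  list(value = E, gradient = grad)
}

#' Regularize coordinates against restraints (toy refinement)
#'
#' Quasi-Newton (BFGS) local minimization of
#' \code{\link{restraint_energy}} with a backtracking (Armijo) line search.
#' The energy never increases between accepted iterations. The
#' Cremer-Pople theta of the pyranose ring is recorded per iteration so
#' conformational trajectories can be plotted.
#'
#' @param coords starting \code{monomer_coords}.
#' @param restraints restraint table.
#' @param density optional \code{density_grid} data term.
#' @param weight density weight.
#' @param max_iter iteration cap; on non-convergence the best-so-far
#'   coordinates are returned with \code{converged = FALSE}.
#' @param tol convergence tolerance on the energy change; default 1e-8.
#' @param ring ring atom names for the theta trajectory; inferred from the
#'   starting coordinates when possible.
#' @return object of class \code{ring_min}: \code{coords}, \code{energy},
#'   \code{trajectory} (data frame iter/energy/theta), \code{converged}.
#' @export
regularize <- function(coords, restraints, density = NULL, weight = 0,
                       max_iter = 200, tol = 1e-8, ring = NULL) {
  if (is.null(ring))
    ring <- tryCatch(detect_ring_coords(coords), error = function(e) NULL)
  nm <- rownames(coords)
  x <- as.numeric(unclass(coords)[, 1:3])
  n <- length(x)
  to_coords <- function(x) {
    m <- matrix(x, ncol = 3, dimnames = list(nm, c("x", "y", "z")))
    as_monomer_coords(m)
  }
  fg <- function(x) {
    e <- restraint_energy(to_coords(x), restraints, density, weight)
    list(f = e$value, g = as.numeric(e$gradient))
  }
  theta_of <- function(x) {
    if (is.null(ring)) return(NA_real_)
    cp <- tryCatch(cremer_pople(to_coords(x), ring), error = function(e) NULL)
    if (is.null(cp) || cp$planar) NA_real_ else cp$theta
  }

  cur <- fg(x)
  if (!is.finite(cur$f)) stop("energy not finite at the starting coordinates")
  H <- diag(n)          # inverse-Hessian approximation
  traj <- data.frame(iter = 0L, energy = cur$f, theta = theta_of(x))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- -as.numeric(H %*% cur$g)
    gTp <- sum(cur$g * p)
    if (gTp > 0) { p <- -cur$g; gTp <- -sum(cur$g^2) }   # reset to descent
    step <- 1
    accepted <- FALSE
    for (ls in 1:40) {
      xn <- x + step * p
      new <- fg(xn)
      if (is.finite(new$f) && new$f <= cur$f + 1e-4 * step * gTp) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no descent possible
    s <- xn - x
    y <- new$g - cur$g
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      H <- (I - rho * outer(s, y)) %*% H %*% (I - rho * outer(y, s)) +
        rho * outer(s, s)
    }
    dE <- cur$f - new$f
    x <- xn
    cur <- new
    traj <- rbind(traj, data.frame(iter = it, energy = cur$f,
                                   theta = theta_of(x)))
    if (dE < tol && sqrt(sum(cur$g^2)) < 1e-4) { converged <- TRUE; break }
  }
  structure(list(coords = to_coords(x), energy = cur$f,
                 trajectory = traj, converged = converged,
                 ring = ring), class = "ring_min")
}

#' @export
print.ring_min <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("ring_min: %d iterations, final energy %.4g, theta %s%s\n",
              last$iter, x$energy,
              if (is.na(last$theta)) "NA" else sprintf("%.1f deg", last$theta),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Plot a regularization trajectory
#'
#' @param x \code{ring_min} result.
#' @param ... passed to \code{plot}.
#' @export
plot.ring_min <- function(x, ...) {
  tr <- x$trajectory
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(tr$iter, tr$energy, type = "l", xlab = "iteration",
                 ylab = "energy", log = "y", ...)
  graphics::plot(tr$iter, tr$theta, type = "l", xlab = "iteration",
                 ylab = expression(theta ~ "(deg)"), ylim = c(0, 180), ...)
  invisible(x)
}
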