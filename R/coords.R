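#' Monomer coordinates
#'
#' A \code{monomer_coords} object is an n x 3 numeric matrix of Cartesian
#' coordinates (Angstrom) with atom names as rownames and an optional
#' per-atom \code{occupancy} attribute. Atom names are stored with
#' surrounding whitespace stripped.
#'
#' @param x numeric matrix (n x 3) with atom-name rownames, or a data frame
#'   with columns \code{name}, \code{x}, \code{y}, \code{z}.
#' @param occupancy optional numeric vector in [0, 1], one per atom.
#' @return an object of class \code{monomer_coords}.
#' @export
as_monomer_coords <- function(x, occupancy = NULL) {
  if (is.data.frame(x)) {
    m <- as.matrix(x[, c("x", "y", "z")])
    rownames(m) <- trimws(as.character(x$name))
    x <- m
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("coordinates must have three columns")
  if (is.null(rownames(x))) stop("coordinates must carry atom-name rownames")
  rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate atom names in coordinates: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (!all(is.finite(x))) stop("non-finite coordinates")
  colnames(x) <- c("x", "y", "z")
  if (!is.null(occupancy)) {
    stopifnot(length(occupancy) == nrow(x))
    attr(x, "occupancy") <- as.numeric(occupancy)
  }
  class(x) <- c("monomer_coords", class(matrix()))
  x
}

#' @export
print.monomer_coords <- function(x, ...) {
  cat(sprintf("monomer_coords: %d atoms\n", nrow(x)))
  print(round(unclass(x)[, 1:3, drop = FALSE], 3))
  invisible(x)
}

## Heavy atoms only (ring analysis ignores hydrogens throughout).
heavy_atoms <- function(coords, elements = NULL) {
  nm <- rownames(coords)
  if (is.null(elements)) {
    keep <- !grepl("^[0-9]*H", nm)   # sugar hydrogens: H1, HO1, 1H6, ...
  } else {
    keep <- !(toupper(elements) %in% c("H", "D"))
  }
  coords[keep, , drop = FALSE]
}

## Apply a rigid motion (rotation matrix R, translation t) to coordinates.
transform_coords <- function(coords, R = diag(3), t = c(0, 0, 0)) {
  out <- unclass(coords)[, 1:3, drop = FALSE] %*% t(R)
  out <- sweep(out, 2, -t)
  rownames(out) <- rownames(coords)
  as_monomer_coords(out, occupancy = attr(coords, "occupancy"))
}

## Random proper rotation matrix (for property tests); uses current RNG.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}
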