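## Gaussian-atom density grids and the masked real-space correlation
## coefficient (RSCC). The density here is a synthetic stand-in: a sum of
## unit-height isotropic Gaussians at the atom centres, not a
## crystallographic 2mFo-DFc map, so RSCC numbers are comparable only
## within this package.

#' Construct a density grid
#'
#' @param origin grid origin (Angstrom, length-3).
#' @param spacing voxel spacing per axis (Angstrom, length-3 or scalar,
#'   > 0).
#' @param values 3D numeric array of density values (arbitrary units).
#' @return object of class \code{density_grid}.
#' @export
density_grid <- function(origin, spacing, values) {
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(all(spacing > 0), length(dim(values)) == 3,
            all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 values = values), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels, spacing %.2f/%.2f/%.2f A\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

## Axis coordinates of a grid.
.grid_axes <- function(g) {
  d <- dim(g$values)
  lapply(1:3, function(k) g$origin[k] + (seq_len(d[k]) - 1) * g$spacing[k])
}

## An empty grid template around a set of coordinates.
#' Empty grid template covering a model
#'
#' @param coords \code{monomer_coords} to cover.
#' @param spacing voxel spacing (Angstrom).
#' @param pad padding beyond the model's bounding box (Angstrom).
#' @return \code{density_grid} of zeros.
#' @export
grid_template <- function(coords, spacing = 0.4, pad = 3.0) {
  m <- unclass(coords)[, 1:3, drop = FALSE]
  lo <- apply(m, 2, min) - pad
  hi <- apply(m, 2, max) + pad
  n <- pmax(2L, ceiling((hi - lo) / spacing) + 1L)
  density_grid(lo, spacing, array(0, dim = n))
}

#' Gaussian-atom model density on a grid
#'
#' Evaluates a sum of isotropic unit-peak Gaussians centred at the atom
#' positions on the template grid. Atoms outside the grid contribute their
#' in-grid tails.
#'
#' @param coords \code{monomer_coords}.
#' @param template \code{density_grid} defining origin/spacing/extent.
#' @param width Gaussian standard deviation (Angstrom); default 0.9.
#' @return \code{density_grid} with the calculated density.
#' @export
calc_density <- function(coords, template, width = 0.9) {
  stopifnot(width > 0)
  ax <- .grid_axes(template)
  d <- dim(template$values)
  vals <- array(0, dim = d)
  m <- unclass(coords)[, 1:3, drop = FALSE]
  inv2w2 <- 1 / (2 * width^2)
  for (a in seq_len(nrow(m))) {
    gx <- exp(-(ax[[1]] - m[a, 1])^2 * inv2w2)
    gy <- exp(-(ax[[2]] - m[a, 2])^2 * inv2w2)
    gz <- exp(-(ax[[3]] - m[a, 3])^2 * inv2w2)
    vals <- vals + outer(outer(gx, gy), gz)
  }
  density_grid(template$origin, template$spacing, vals)
}

## Logical mask of voxels within `radius` of any atom.
.grid_mask <- function(g, coords, radius) {
  ax <- .grid_axes(g)
  d <- dim(g$values)
  m <- unclass(coords)[, 1:3, drop = FALSE]
  mask <- array(FALSE, dim = d)
  r2 <- radius^2
  for (a in seq_len(nrow(m))) {
    dx2 <- (ax[[1]] - m[a, 1])^2
    dy2 <- (ax[[2]] - m[a, 2])^2
    dz2 <- (ax[[3]] - m[a, 3])^2
    mask <- mask | (outer(outer(dx2, dy2, "+"), dz2, "+") <= r2)
  }
  mask
}

#' Masked real-space correlation coefficient
#'
#' Pearson correlation between an observed and a calculated density grid
#' over the voxels within \code{mask_radius} of any atom of the mask
#' model. Both grids must share origin, spacing and extent. Invariant
#' under positive affine rescaling of either grid.
#'
#' @param obs,calc \code{density_grid} objects on the same grid.
#' @param mask_centre \code{monomer_coords} defining the mask region
#'   (typically the sugar model).
#' @param mask_radius mask radius around atoms (Angstrom); default 2.5.
#' @return correlation in [-1, 1].
#' @export
rscc <- function(obs, calc, mask_centre, mask_radius = 2.5) {
  if (!isTRUE(all.equal(obs$origin, calc$origin)) ||
      !isTRUE(all.equal(obs$spacing, calc$spacing)) ||
      !identical(dim(obs$values), dim(calc$values)))
    stop("observed and calculated grids do not share geometry")
  mask <- .grid_mask(obs, mask_centre, mask_radius)
  if (sum(mask) < 2) stop("mask selects fewer than 2 voxels")
  a <- obs$values[mask]
  b <- calc$values[mask]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12)
    stop("undefined RSCC: zero variance inside the mask")
  stats::cor(a, b)
}

## ---- CCP4/MRC map I/O (mode 2, float32, orthogonal axes) -----------------

#' Write a density grid as a CCP4/MRC map
#'
#' Minimal mode-2 (float32) writer for orthogonal grids: axis order X,Y,Z,
#' cell dimensions from spacing times extent, origin stored in the
#' ORIGIN fields. Sufficient for exchanging the package's synthetic grids
#' with molecular-graphics software.
#'
#' @param g \code{density_grid}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_ccp4_map <- function(g, path) {
  d <- dim(g$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                          # NX NY NZ
  wi(2)                          # MODE 2 = float32
  wi(c(0, 0, 0))                 # NXSTART..
  wi(d - 1L)                     # MX MY MZ (sampling intervals)
  wf((d - 1L) * g$spacing)       # cell a b c
  wf(c(90, 90, 90))              # alpha beta gamma
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS
  wf(c(min(g$values), max(g$values), mean(g$values)))
  wi(1)                          # ISPG
  wi(0)                          # NSYMBT
  wi(rep(0, 25))                 # extra
  wf(g$origin)                   # ORIGIN x y z (MRC2014)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(g$values)))               # RMS
  wi(0)                          # NLABL
  writeBin(raw(800), con)        # labels
  wf(as.numeric(g$values))       # column-major = x fastest, matches MAPC
  invisible(path)
}

#' Read a CCP4/MRC map into a density grid
#'
#' Counterpart of \code{\link{write_ccp4_map}}; reads little-endian mode-2
#' maps with axis order X,Y,Z.
#'
#' @param path map file.
#' @return \code{density_grid}.
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported map mode ", mode, " (only mode 2 float32)")
  ri(3)                          # NXSTART
  m <- ri(3)                     # MX MY MZ
  cell <- rf(3)
  rf(3)                          # angles
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported axis order (expected X,Y,Z)")
  rf(3); ri(1)
  nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  seek(con, 1024 + nsymbt, origin = "start")  # skip MAP/stamp/RMS/labels
  vals <- rf(prod(d))
  spacing <- ifelse(m > 0, cell / m, 1)
  density_grid(origin, spacing, array(vals, dim = d))
}
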