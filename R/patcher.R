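## Patching restraint dictionaries with conformation-aware torsion
## restraints: the six endocyclic torsions become unimodal `ring_1..ring_6`
## restraints (tight sigma, period 1) with targets measured from the
## low-energy conformer coordinates, while every other heavy-atom torsion is
## renamed `tors_<k>` and kept at the looser default sigma. Generic targets
## (e.g. 60 degrees for any sp3-sp3 bond) do not fit a pyranose: the
## endocyclic oxygen makes the ring bond lengths unequal, so the measured
## torsions (53.65 degrees along O5-C1-C2-C3 for a low-energy GlcNAc
## conformer, for example) differ from the generic value.

## Canonical undirected key for a torsion's atom quadruple.
.torsion_key <- function(a1, a2, a3, a4) {
  fwd <- paste(a1, a2, a3, a4, sep = "|")
  rev <- paste(a4, a3, a2, a1, sep = "|")
  ifelse(fwd <= rev, fwd, rev)
}

#' Patch a dictionary with measured, conformation-aware torsion restraints
#'
#' Replaces the torsion section of a restraint dictionary: the six
#' endocyclic torsions are emitted as \code{ring_1..ring_6} in ring order
#' (starting at the ring-oxygen to anomeric-carbon bond), each with target
#' equal to the torsion measured from the conformer coordinates,
#' \code{sigma = sigma_ring} and period 1 (unimodal). Every other torsion
#' of the input keeps its atom quadruple and periodicity, is renamed
#' \code{tors_<k>}, has its target re-measured from the conformer when all
#' four atoms are present, and receives \code{sigma = sigma_other} unless
#' its input sigma was already smaller. Torsions involving hydrogens are
#' dropped. Bonds, angles, chiralities, planes and the component type pass
#' through unchanged, so patching is idempotent.
#'
#' @param d a \code{\link{restraint_dictionary}} for a pyranose.
#' @param coords conformer coordinates (defaults to the dictionary's own
#'   model coordinates).
#' @param sigma_ring sigma (degrees) for the six unimodal ring torsions;
#'   default 3.0 (6.0 and 10.0 are the other grid values explored when
#'   selecting the default).
#' @param sigma_other sigma (degrees) for all remaining torsions;
#'   default 10.0.
#' @return the patched \code{restraint_dictionary}.
#' @export
patch_dictionary <- function(d, coords = d$model_coords,
                             sigma_ring = 3.0, sigma_other = 10.0) {
  if (is.null(coords))
    stop("no conformer coordinates: supply 'coords' or include model ",
         "coordinates in the dictionary")
  ring <- detect_ring(d)
  missing <- setdiff(ring, rownames(coords))
  if (length(missing))
    stop("conformer coordinates lack ring atom(s): ",
         paste(missing, collapse = ", "))

  tors_meas <- ring_torsions(coords, ring)
  idx <- function(k) ((k - 1) %% 6) + 1
  ring_rows <- do.call(rbind, lapply(1:6, function(k) {
    quad <- ring[c(idx(k - 1), idx(k), idx(k + 1), idx(k + 2))]
    data.frame(id = paste0("ring_", k),
               atom1 = quad[1], atom2 = quad[2], atom3 = quad[3],
               atom4 = quad[4], value = unname(tors_meas[k]),
               sigma = sigma_ring, period = 1L, stringsAsFactors = FALSE)
  }))
  ring_keys <- .torsion_key(ring_rows$atom1, ring_rows$atom2,
                            ring_rows$atom3, ring_rows$atom4)

  elem <- setNames(toupper(trimws(ifelse(is.na(d$atoms$element),
                                         substr(d$atoms$name, 1, 1),
                                         d$atoms$element))), d$atoms$name)
  other <- d$torsions
  if (nrow(other)) {
    keys <- .torsion_key(other$atom1, other$atom2, other$atom3, other$atom4)
    is_h <- apply(other[, c("atom1", "atom2", "atom3", "atom4")], 1,
                  function(a) any(elem[a] %in% c("H", "D")))
    other <- other[!(keys %in% ring_keys) & !is_h, , drop = FALSE]
  }
  if (nrow(other)) {
    for (i in seq_len(nrow(other))) {
      quad <- unlist(other[i, c("atom1", "atom2", "atom3", "atom4")])
      if (all(quad %in% rownames(coords))) {
        xyz <- unclass(.coords_of(coords, quad))
        other$value[i] <- dihedral_angle(xyz[1, 1:3], xyz[2, 1:3],
                                         xyz[3, 1:3], xyz[4, 1:3])
      }
      if (is.na(other$sigma[i]) || other$sigma[i] > sigma_other)
        other$sigma[i] <- sigma_other
    }
    other$id <- paste0("tors_", seq_len(nrow(other)))
  }

  d$torsions <- rbind(ring_rows, other)
  rownames(d$torsions) <- NULL
  check_dictionary(d)
}

#' Compare the torsion sections of two dictionaries
#'
#' Tabulates per-torsion deltas between an old and a new dictionary for the
#' same component, keyed by the (undirected) atom quadruple, and flags
#' replaced old-style uniform-sigma torsions (the LIBCHECK-era entries all
#' carried sigma 20.0).
#'
#' @param old,new \code{restraint_dictionary} objects with matching
#'   \code{comp_id}.
#' @param legacy_sigma sigma value regarded as the legacy uniform
#'   uncertainty; default 20.0 degrees.
#' @return data frame (class \code{torsion_comparison}) with one row per
#'   atom quadruple in either dictionary: ids, values, sigmas, periods on
#'   both sides, their deltas, and \code{legacy_replaced}.
#' @export
compare_dictionaries <- function(old, new, legacy_sigma = 20.0) {
  if (!identical(old$comp_id, new$comp_id))
    stop("component ids differ: ", old$comp_id, " vs ", new$comp_id)
  key_of <- function(t) if (nrow(t)) .torsion_key(t$atom1, t$atom2, t$atom3, t$atom4) else character(0)
  ko <- key_of(old$torsions)
  kn <- key_of(new$torsions)
  keys <- union(ko, kn)
  row_for <- function(t, k, keys) {
    i <- match(keys, k)
    data.frame(id = t$id[i], value = t$value[i], sigma = t$sigma[i],
               period = t$period[i], stringsAsFactors = FALSE)
  }
  o <- row_for(old$torsions, ko, keys)
  n <- row_for(new$torsions, kn, keys)
  out <- data.frame(
    atoms = gsub("\\|", "-", keys),
    old_id = o$id, new_id = n$id,
    old_value = o$value, new_value = n$value,
    delta_value = wrap_deg(n$value - o$value),
    old_sigma = o$sigma, new_sigma = n$sigma,
    delta_sigma = n$sigma - o$sigma,
    old_period = o$period, new_period = n$period,
    legacy_replaced = !is.na(o$sigma) & o$sigma == legacy_sigma &
      !is.na(n$sigma) & n$sigma != legacy_sigma,
    stringsAsFactors = FALSE)
  ## identical rows carry no delta: drop them from the report body but keep
  ## the full table as an attribute
  same <- !is.na(out$old_value) & !is.na(out$new_value) &
    abs(out$delta_value) < 1e-9 & out$delta_sigma == 0 &
    out$old_period == out$new_period & out$old_id == out$new_id
  res <- out[!same, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_rows") <- out
  class(res) <- c("torsion_comparison", class(res))
  res
}

#' @export
print.torsion_comparison <- function(x, ...) {
  all_rows <- attr(x, "all_rows")
  cat(sprintf("torsion comparison: %d quadruples, %d changed, %d legacy (sigma 20) replaced\n",
              nrow(all_rows), nrow(x), sum(x$legacy_replaced)))
  if (nrow(x)) print.data.frame(x, digits = 4)
  invisible(x)
}
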