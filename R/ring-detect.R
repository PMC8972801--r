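## Pyranose ring perception from dictionary connectivity. Detection is
## graph-based (cycles of the bond graph), not name-based, so remediated or
## legacy atom names and ketopyranoses are all handled; names are used only
## for tie-breaking and reporting.

## All simple 6-cycles of an adjacency list (small monomer graphs only).
.six_cycles <- function(adj) {
  verts <- names(adj)
  cycles <- list()
  seen <- character(0)
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (length(path) == 6) {
        if (nb == path[1]) {
          key <- paste(sort(path), collapse = "|")
          if (!(key %in% seen)) {
            seen <<- c(seen, key)
            cycles[[length(cycles) + 1]] <<- path
          }
        }
      } else if (!(nb %in% path) && nb > path[1]) {
        # extending only with vertices ordered after the start vertex makes
        # the start the cycle minimum, so each cycle is enumerated from one
        # root only (both directions; deduplicated by the sorted key)
        dfs(c(path, nb))
      }
    }
  }
  for (v in verts) dfs(v)
  cycles
}

#' Detect the pyranose ring of a dictionary
#'
#' Finds the unique six-membered cycle of the heavy-atom bond graph made of
#' exactly one oxygen and five carbons, and orients it: position 1 is the
#' ring oxygen, position 2 the anomeric carbon (the ring carbon bonded to
#' the most exocyclic oxygen atoms; ties broken by the lower-numbered atom
#' name), and the traversal proceeds from the oxygen through the anomeric
#' carbon around the ring. For an aldopyranose with wwPDB names this yields
#' \code{O5 C1 C2 C3 C4 C5}.
#'
#' @param d a \code{\link{restraint_dictionary}} (bonds and elements used).
#' @return character vector of six atom names in ring order, with the
#'   anomeric carbon as attribute \code{"anomeric"}.
#' @export
detect_ring <- function(d) {
  atoms <- d$atoms
  elem <- toupper(trimws(ifelse(is.na(atoms$element),
                                substr(atoms$name, 1, 1), atoms$element)))
  heavy <- atoms$name[!(elem %in% c("H", "D"))]
  el <- setNames(elem, atoms$name)
  bonds <- d$bonds[d$bonds$atom1 %in% heavy & d$bonds$atom2 %in% heavy, ]
  adj <- lapply(setNames(nm = heavy), function(a)
    sort(unique(c(bonds$atom2[bonds$atom1 == a], bonds$atom1[bonds$atom2 == a]))))
  cycles <- .six_cycles(adj)
  ok <- Filter(function(cy) {
    e <- el[cy]
    sum(e == "O") == 1 && sum(e == "C") == 5
  }, cycles)
  if (length(ok) == 0)
    stop("not a pyranose: no six-membered ring of one oxygen and five carbons")
  keys <- vapply(ok, function(cy) paste(sort(cy), collapse = "|"), "")
  ok <- ok[!duplicated(keys)]
  if (length(ok) > 1)
    stop("ambiguous ring: more than one candidate pyranose ring found")
  cy <- ok[[1]]
  oxy <- cy[el[cy] == "O"]
  carbons <- setdiff(cy, oxy)

  ## anomeric carbon: ring carbon with most exocyclic oxygens
  n_exo_o <- vapply(carbons, function(a) {
    nb <- adj[[a]]
    sum(el[setdiff(nb, cy)] == "O")
  }, numeric(1))
  atom_number <- function(a) {
    n <- suppressWarnings(as.numeric(gsub("[^0-9]", "", a)))
    ifelse(is.na(n), Inf, n)
  }
  cand <- carbons[n_exo_o == max(n_exo_o)]
  anomeric <- cand[order(vapply(cand, atom_number, numeric(1)), cand)][1]

  ## orient: oxygen first, then proceed through the anomeric carbon
  pos_o <- match(oxy, cy)
  ring <- c(cy[pos_o:6], cy[seq_len(pos_o - 1)])
  nbrs_in_ring <- c(ring[2], ring[6])
  if (!(anomeric %in% nbrs_in_ring))
    stop("internal error: anomeric carbon not adjacent to the ring oxygen")
  if (ring[2] != anomeric) ring <- c(ring[1], rev(ring[-1]))
  attr(ring, "anomeric") <- anomeric
  ring
}

## Distance-based bond perception for bare coordinates (used when no
## dictionary is available, e.g. by distort_ring). Heavy atoms only.
infer_bonds <- function(coords, cutoff = 1.8) {
  hc <- heavy_atoms(coords)
  nm <- rownames(hc)
  n <- nrow(hc)
  a1 <- character(0); a2 <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (.vnorm(unclass(hc)[i, 1:3] - unclass(hc)[j, 1:3]) <= cutoff) {
        a1 <- c(a1, nm[i]); a2 <- c(a2, nm[j])
      }
    }
  }
  data.frame(atom1 = a1, atom2 = a2, order = "single",
             value = NA_real_, sigma = NA_real_, stringsAsFactors = FALSE)
}

## Ring detection straight from coordinates via inferred connectivity.
detect_ring_coords <- function(coords, cutoff = 1.8) {
  hc <- heavy_atoms(coords)
  atoms <- data.frame(name = rownames(hc),
                      element = substr(rownames(hc), 1, 1),
                      charge = 0, stringsAsFactors = FALSE)
  d <- restraint_dictionary(comp_id = "TMP", atoms = atoms,
                            bonds = infer_bonds(coords, cutoff))
  detect_ring(d)
}
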