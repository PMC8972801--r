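## Monomer-library restraint-dictionary CIF I/O.
##
## The dialect read and written here is the CCP4 monomer-library chem_comp
## dialect: a `data_comp_list` block with a `_chem_comp` loop (id,
## three_letter_code, name, group, atom counts) followed by a
## `data_comp_<ID>` block holding the per-category loops
##   _chem_comp_atom  (comp_id, atom_id, type_symbol, charge [, x, y, z])
##   _chem_comp_bond  (comp_id, atom_id_1, atom_id_2, type,
##                     value_dist, value_dist_esd)
##   _chem_comp_angle (comp_id, atom_id_1..3, value_angle, value_angle_esd)
##   _chem_comp_tor   (comp_id, id, atom_id_1..4, value_angle,
##                     value_angle_esd, period)
##   _chem_comp_chir  (comp_id, id, atom_id_centre, atom_id_1..3,
##                     volume_sign)
##   _chem_comp_plane_atom (comp_id, plane_id, atom_id, dist_esd)
## Parsing keys on tag names, so column order and comment lines are
## irrelevant. Loops of any other category are preserved verbatim and
## re-emitted on write, so patching never destroys information.

## ---- tokenizer -----------------------------------------------------------

.cif_tokenize <- function(lines) {
  toks <- character(0)
  lno <- integer(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, ";")) {
      # minimal multi-line value support: treat the whole line as one token
      toks <- c(toks, sub("^;", "", line))
      lno <- c(lno, i)
      next
    }
    out <- character(0)
    n <- nchar(line)
    k <- 1
    while (k <= n) {
      ch <- substr(line, k, k)
      if (ch %in% c(" ", "\t")) { k <- k + 1; next }
      if (ch == "#") break
      if (ch %in% c("'", '"')) {
        close <- regexpr(ch, substr(line, k + 1, n), fixed = TRUE)
        if (close < 0) stop("unterminated quote on line ", i)
        out <- c(out, substr(line, k + 1, k + close - 1))
        k <- k + close + 1
      } else {
        rest <- substr(line, k, n)
        m <- regexpr("^[^ \t]+", rest)
        tok <- regmatches(rest, m)
        out <- c(out, tok)
        k <- k + attr(m, "match.length")
      }
    }
    if (length(out)) {
      toks <- c(toks, out)
      lno <- c(lno, rep(i, length(out)))
    }
  }
  list(tokens = toks, lines = lno)
}

## Parse CIF text into blocks; each block has $items (named character) and
## $loops (list of character data frames keyed by category, with attribute
## "tags" holding the full tag names).
.cif_parse <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  tk <- .cif_tokenize(lines)
  toks <- tk$tokens
  lns <- tk$lines
  blocks <- list()
  cur <- NULL
  cur_name <- NULL
  i <- 1
  n <- length(toks)
  flush <- function() {
    if (!is.null(cur)) blocks[[cur_name]] <<- cur
  }
  while (i <= n) {
    t <- toks[i]
    if (grepl("^data_", t)) {
      flush()
      cur_name <- sub("^data_", "", t)
      cur <- list(items = character(0), loops = list())
      i <- i + 1
    } else if (tolower(t) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= n && startsWith(toks[i], "_")) {
        tags <- c(tags, toks[i])
        i <- i + 1
      }
      if (!length(tags)) stop("malformed loop: no tags (line ", lns[i - 1], ")")
      vals <- character(0)
      while (i <= n && !startsWith(toks[i], "_") &&
             tolower(toks[i]) != "loop_" && !grepl("^data_", toks[i])) {
        vals <- c(vals, toks[i])
        i <- i + 1
      }
      cat_name <- sub("\\..*$", "", sub("^_", "", tags[1]))
      if (length(vals) %% length(tags) != 0)
        stop("malformed loop '", cat_name, "': ", length(vals),
             " values for ", length(tags), " columns")
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- sub("^_[^.]*\\.", "", tags)
      attr(df, "tags") <- tags
      if (is.null(cur)) { cur <- list(items = character(0), loops = list()); cur_name <- "unnamed" }
      cur$loops[[cat_name]] <- df
    } else if (startsWith(t, "_")) {
      if (i + 1 > n) stop("dangling item ", t)
      if (is.null(cur)) { cur <- list(items = character(0), loops = list()); cur_name <- "unnamed" }
      cur$items[[t]] <- toks[i + 1]
      i <- i + 2
    } else {
      stop("unexpected token '", t, "' at line ", lns[i])
    }
  }
  flush()
  blocks
}

.cif_num <- function(x) {
  x[x %in% c(".", "?")] <- NA
  suppressWarnings(as.numeric(x))
}

.cif_str <- function(x) {
  x[x %in% c(".", "?")] <- NA
  x
}

## ---- restraint_dictionary construction and checking ----------------------

#' Restraint dictionary constructor
#'
#' Assembles and integrity-checks a restraint dictionary for one monomer.
#' Every atom referenced by a bond, angle, torsion, chirality or plane must
#' exist in \code{atoms}, and atom names must be unique.
#'
#' @param comp_id three-letter component code.
#' @param comp_name free-text component name.
#' @param comp_type component type; \code{"pyranose"} for aldopyranoses,
#'   \code{"ketopyranose"} for ketopyranoses, anything else passed through
#'   verbatim.
#' @param atoms data frame with columns \code{name}, \code{element},
#'   \code{charge}.
#' @param bonds data frame \code{atom1, atom2, order, value, sigma}
#'   (Angstrom).
#' @param angles data frame \code{atom1, atom2, atom3, value, sigma}
#'   (degrees).
#' @param torsions data frame \code{id, atom1..atom4, value, sigma, period};
#'   ids beginning \code{ring_} mark unimodal endocyclic restraints.
#' @param chiralities data frame \code{id, centre, atom1..atom3, sign} with
#'   sign in \code{positive/negative/both}.
#' @param planes data frame \code{plane_id, atom, sigma}.
#' @param model_coords optional \code{\link{as_monomer_coords}} object with
#'   a low-energy conformer.
#' @param extra named list of opaque loops (preserved on write).
#' @return object of class \code{restraint_dictionary}.
#' @export
restraint_dictionary <- function(comp_id, comp_name = comp_id,
                                 comp_type = "pyranose",
                                 atoms,
                                 bonds = NULL, angles = NULL,
                                 torsions = NULL, chiralities = NULL,
                                 planes = NULL, model_coords = NULL,
                                 extra = list()) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df
  }
  d <- structure(list(
    comp_id = comp_id, comp_name = comp_name, comp_type = comp_type,
    atoms = atoms,
    bonds = if (is.null(bonds)) empty(c("atom1", "atom2", "order", "value", "sigma")) else bonds,
    angles = if (is.null(angles)) empty(c("atom1", "atom2", "atom3", "value", "sigma")) else angles,
    torsions = if (is.null(torsions)) empty(c("id", "atom1", "atom2", "atom3", "atom4", "value", "sigma", "period")) else torsions,
    chiralities = if (is.null(chiralities)) empty(c("id", "centre", "atom1", "atom2", "atom3", "sign")) else chiralities,
    planes = if (is.null(planes)) empty(c("plane_id", "atom", "sigma")) else planes,
    model_coords = model_coords,
    extra = extra), class = "restraint_dictionary")
  check_dictionary(d)
  d
}

#' Integrity-check a restraint dictionary
#'
#' Verifies the dictionary invariants: unique atom names, every referenced
#' atom present, positive torsion sigmas and periods, chirality centres
#' distinct from their neighbours.
#'
#' @param d a \code{restraint_dictionary}.
#' @return \code{d}, invisibly; stops with a diagnostic on violation.
#' @export
check_dictionary <- function(d) {
  nm <- d$atoms$name
  if (anyDuplicated(nm))
    stop("integrity error: duplicate atom names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ref <- function(what, atoms) {
    bad <- setdiff(atoms, nm)
    if (length(bad))
      stop("integrity error: ", what, " references unknown atom(s): ",
           paste(bad, collapse = ", "))
  }
  ref("bond", unlist(d$bonds[, c("atom1", "atom2")]))
  ref("angle", unlist(d$angles[, c("atom1", "atom2", "atom3")]))
  ref("torsion", unlist(d$torsions[, c("atom1", "atom2", "atom3", "atom4")]))
  ref("chirality", unlist(d$chiralities[, c("centre", "atom1", "atom2", "atom3")]))
  ref("plane", d$planes$atom)
  if (nrow(d$torsions)) {
    if (any(!is.finite(d$torsions$sigma)) || any(d$torsions$sigma <= 0))
      stop("integrity error: torsion sigma must be > 0")
    if (any(d$torsions$period < 1))
      stop("integrity error: torsion period must be >= 1")
  }
  if (nrow(d$chiralities)) {
    for (i in seq_len(nrow(d$chiralities))) {
      row <- d$chiralities[i, ]
      nb <- c(row$atom1, row$atom2, row$atom3)
      if (row$centre %in% nb || anyDuplicated(nb))
        stop("integrity error: chirality ", row$id,
             " centre/neighbours not distinct")
    }
  }
  if (!is.null(d$model_coords)) {
    bad <- setdiff(rownames(d$model_coords), nm)
    if (length(bad))
      stop("integrity error: model coordinates for unknown atom(s): ",
           paste(bad, collapse = ", "))
  }
  invisible(d)
}

#' @export
print.restraint_dictionary <- function(x, ...) {
  cat(sprintf("restraint_dictionary: %s (%s), type '%s'\n",
              x$comp_id, x$comp_name, x$comp_type))
  cat(sprintf("  %d atoms, %d bonds, %d angles, %d torsions (%d ring), %d chiralities, %d planes%s\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              sum(grepl("^ring_", x$torsions$id)),
              nrow(x$chiralities), nrow(x$planes),
              if (!is.null(x$model_coords)) ", model coordinates present" else ""))
  invisible(x)
}

## ---- reader --------------------------------------------------------------

#' Read a restraint dictionary entry
#'
#' Parses one monomer-library-style CIF component entry. The source must
#' contain exactly one component entry with at least atom and bond loops;
#' missing optional loops yield empty tables. Torsion ids, values, sigmas
#' and periods are preserved exactly as read.
#'
#' @param source CIF text (single string or character vector of lines) or a
#'   file path.
#' @return a \code{\link{restraint_dictionary}}.
#' @export
read_dictionary <- function(source) {
  text <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else source
  blocks <- .cif_parse(text)
  comp_blocks <- blocks[grepl("^comp_", names(blocks)) &
                          names(blocks) != "comp_list"]
  if (!length(comp_blocks)) {
    # fall back: any block holding a chem_comp_atom loop
    comp_blocks <- Filter(function(b) "chem_comp_atom" %in% names(b$loops),
                          blocks)
  }
  if (length(comp_blocks) != 1)
    stop("expected exactly one component entry, found ", length(comp_blocks))
  blk <- comp_blocks[[1]]

  meta <- list(id = NA, name = NA, group = NA)
  if ("comp_list" %in% names(blocks)) {
    cl <- blocks[["comp_list"]]$loops[["chem_comp"]]
    if (!is.null(cl) && nrow(cl) >= 1) {
      meta$id <- .cif_str(cl$id[1])
      meta$name <- .cif_str(cl$name[1])
      meta$group <- .cif_str(cl$group[1])
    }
  }

  at <- blk$loops[["chem_comp_atom"]]
  if (is.null(at)) stop("parse error in loop 'chem_comp_atom': loop missing")
  atoms <- data.frame(name = trimws(at$atom_id),
                      element = if ("type_symbol" %in% names(at)) at$type_symbol else NA,
                      charge = if ("charge" %in% names(at)) .cif_num(at$charge) else 0,
                      stringsAsFactors = FALSE)
  atoms$charge[is.na(atoms$charge)] <- 0

  model_coords <- NULL
  xyz_cols <- if (all(c("x", "y", "z") %in% names(at))) c("x", "y", "z")
  else if (all(c("model_Cartn_x", "model_Cartn_y", "model_Cartn_z") %in% names(at)))
    c("model_Cartn_x", "model_Cartn_y", "model_Cartn_z")
  else NULL
  if (!is.null(xyz_cols)) {
    xyz <- vapply(xyz_cols, function(cn) .cif_num(at[[cn]]), numeric(nrow(at)))
    if (!anyNA(xyz)) {
      m <- matrix(xyz, ncol = 3)
      rownames(m) <- atoms$name
      model_coords <- as_monomer_coords(m)
    }
  }

  bd <- blk$loops[["chem_comp_bond"]]
  if (is.null(bd)) stop("parse error in loop 'chem_comp_bond': loop missing")
  bonds <- data.frame(atom1 = trimws(bd$atom_id_1), atom2 = trimws(bd$atom_id_2),
                      order = if ("type" %in% names(bd)) bd$type else "single",
                      value = .cif_num(bd$value_dist),
                      sigma = .cif_num(bd$value_dist_esd),
                      stringsAsFactors = FALSE)

  an <- blk$loops[["chem_comp_angle"]]
  angles <- if (is.null(an)) NULL else
    data.frame(atom1 = trimws(an$atom_id_1), atom2 = trimws(an$atom_id_2),
               atom3 = trimws(an$atom_id_3),
               value = .cif_num(an$value_angle),
               sigma = .cif_num(an$value_angle_esd), stringsAsFactors = FALSE)

  tr <- blk$loops[["chem_comp_tor"]]
  torsions <- if (is.null(tr)) NULL else
    data.frame(id = tr$id,
               atom1 = trimws(tr$atom_id_1), atom2 = trimws(tr$atom_id_2),
               atom3 = trimws(tr$atom_id_3), atom4 = trimws(tr$atom_id_4),
               value = .cif_num(tr$value_angle),
               sigma = .cif_num(tr$value_angle_esd),
               period = as.integer(.cif_num(tr$period)),
               stringsAsFactors = FALSE)

  ch <- blk$loops[["chem_comp_chir"]]
  chiralities <- if (is.null(ch)) NULL else
    data.frame(id = ch$id, centre = trimws(ch$atom_id_centre),
               atom1 = trimws(ch$atom_id_1), atom2 = trimws(ch$atom_id_2),
               atom3 = trimws(ch$atom_id_3),
               sign = ch$volume_sign, stringsAsFactors = FALSE)

  pl <- blk$loops[["chem_comp_plane_atom"]]
  planes <- if (is.null(pl)) NULL else
    data.frame(plane_id = pl$plane_id, atom = trimws(pl$atom_id),
               sigma = .cif_num(pl$dist_esd), stringsAsFactors = FALSE)

  known <- c("chem_comp_atom", "chem_comp_bond", "chem_comp_angle",
             "chem_comp_tor", "chem_comp_chir", "chem_comp_plane_atom")
  extra <- blk$loops[setdiff(names(blk$loops), known)]

  comp_id <- if (!is.na(meta$id)) meta$id else
    if ("comp_id" %in% names(at)) at$comp_id[1] else
      sub("^comp_", "", names(comp_blocks)[1])

  restraint_dictionary(
    comp_id = comp_id,
    comp_name = if (!is.na(meta$name)) meta$name else comp_id,
    comp_type = if (!is.na(meta$group)) meta$group else "non-polymer",
    atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
    chiralities = chiralities, planes = planes,
    model_coords = model_coords, extra = extra)
}

## ---- writer --------------------------------------------------------------

.fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), ".", formatC(x, format = "f", digits = digits))
}

.cif_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "."
  needs <- grepl("[ \t']", x) | x == ""
  x[needs] <- paste0('"', x[needs], '"')
  x
}

.emit_loop <- function(tags, cols) {
  rows <- do.call(paste, c(lapply(cols, .cif_quote), sep = " "))
  c("loop_", tags, rows)
}

#' Write a restraint dictionary entry as CIF text
#'
#' Emits the dictionary in the monomer-library dialect. The torsion loop
#' lists ring torsions first, in ring order, then the remaining torsions.
#' Numeric fields use fixed decimal places (3 for Angstrom and degree
#' quantities) so that re-reading reproduces the values exactly; a
#' write-read-write cycle is byte-identical.
#'
#' @param d a \code{\link{restraint_dictionary}} (invariants are checked;
#'   writing is refused with a diagnostic on violation).
#' @param dest optional path; when omitted the CIF text is returned.
#' @return the CIF text as a character vector of lines (invisibly when
#'   \code{dest} is given).
#' @export
write_dictionary <- function(d, dest = NULL) {
  check_dictionary(d)
  out <- c(
    "# restraint dictionary entry written by sugarpucker",
    "data_comp_list",
    "loop_",
    "_chem_comp.id", "_chem_comp.three_letter_code", "_chem_comp.name",
    "_chem_comp.group", "_chem_comp.number_atoms_all",
    "_chem_comp.number_atoms_nh", "_chem_comp.desc_level",
    paste(.cif_quote(d$comp_id), .cif_quote(d$comp_id), .cif_quote(d$comp_name),
          .cif_quote(d$comp_type), nrow(d$atoms),
          sum(!grepl("^H$|^D$", d$atoms$element)), "."),
    "",
    paste0("data_comp_", d$comp_id))

  has_xyz <- !is.null(d$model_coords) &&
    all(d$atoms$name %in% rownames(d$model_coords))
  atom_tags <- c("_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
                 "_chem_comp_atom.type_symbol", "_chem_comp_atom.charge")
  atom_cols <- list(rep(d$comp_id, nrow(d$atoms)), d$atoms$name,
                    d$atoms$element, .fmt_num(as.numeric(d$atoms$charge), 3))
  if (has_xyz) {
    xyz <- unclass(d$model_coords)[d$atoms$name, , drop = FALSE]
    atom_tags <- c(atom_tags, "_chem_comp_atom.x", "_chem_comp_atom.y",
                   "_chem_comp_atom.z")
    atom_cols <- c(atom_cols, list(.fmt_num(xyz[, 1]), .fmt_num(xyz[, 2]),
                                   .fmt_num(xyz[, 3])))
  }
  out <- c(out, .emit_loop(atom_tags, atom_cols))

  if (nrow(d$bonds))
    out <- c(out, .emit_loop(
      c("_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
        "_chem_comp_bond.atom_id_2", "_chem_comp_bond.type",
        "_chem_comp_bond.value_dist", "_chem_comp_bond.value_dist_esd"),
      list(rep(d$comp_id, nrow(d$bonds)), d$bonds$atom1, d$bonds$atom2,
           d$bonds$order, .fmt_num(d$bonds$value), .fmt_num(d$bonds$sigma))))

  if (nrow(d$angles))
    out <- c(out, .emit_loop(
      c("_chem_comp_angle.comp_id", "_chem_comp_angle.atom_id_1",
        "_chem_comp_angle.atom_id_2", "_chem_comp_angle.atom_id_3",
        "_chem_comp_angle.value_angle", "_chem_comp_angle.value_angle_esd"),
      list(rep(d$comp_id, nrow(d$angles)), d$angles$atom1, d$angles$atom2,
           d$angles$atom3, .fmt_num(d$angles$value), .fmt_num(d$angles$sigma))))

  if (nrow(d$torsions)) {
    tor <- d$torsions
    ring_first <- order(!grepl("^ring_", tor$id), seq_len(nrow(tor)))
    tor <- tor[ring_first, , drop = FALSE]
    out <- c(out, .emit_loop(
      c("_chem_comp_tor.comp_id", "_chem_comp_tor.id",
        "_chem_comp_tor.atom_id_1", "_chem_comp_tor.atom_id_2",
        "_chem_comp_tor.atom_id_3", "_chem_comp_tor.atom_id_4",
        "_chem_comp_tor.value_angle", "_chem_comp_tor.value_angle_esd",
        "_chem_comp_tor.period"),
      list(rep(d$comp_id, nrow(tor)), tor$id, tor$atom1, tor$atom2,
           tor$atom3, tor$atom4, .fmt_num(tor$value), .fmt_num(tor$sigma),
           as.character(tor$period))))
  }

  if (nrow(d$chiralities))
    out <- c(out, .emit_loop(
      c("_chem_comp_chir.comp_id", "_chem_comp_chir.id",
        "_chem_comp_chir.atom_id_centre", "_chem_comp_chir.atom_id_1",
        "_chem_comp_chir.atom_id_2", "_chem_comp_chir.atom_id_3",
        "_chem_comp_chir.volume_sign"),
      list(rep(d$comp_id, nrow(d$chiralities)), d$chiralities$id,
           d$chiralities$centre, d$chiralities$atom1, d$chiralities$atom2,
           d$chiralities$atom3, d$chiralities$sign)))

  if (nrow(d$planes))
    out <- c(out, .emit_loop(
      c("_chem_comp_plane_atom.comp_id", "_chem_comp_plane_atom.plane_id",
        "_chem_comp_plane_atom.atom_id", "_chem_comp_plane_atom.dist_esd"),
      list(rep(d$comp_id, nrow(d$planes)), d$planes$plane_id,
           d$planes$atom, .fmt_num(d$planes$sigma))))

  for (cat_name in names(d$extra)) {
    df <- d$extra[[cat_name]]
    out <- c(out, .emit_loop(attr(df, "tags"),
                             lapply(df, as.character)))
  }

  if (!is.null(dest)) {
    writeLines(out, dest)
    return(invisible(out))
  }
  out
}

## ---- coordinate readers --------------------------------------------------

#' Read monomer coordinates for one component
#'
#' Extracts per-residue coordinates for a component from PDB-format records
#' or from CCD-style component CIF blocks. PDB input is parsed with
#' \pkg{bio3d}; one \code{monomer_coords} is returned per residue instance
#' of \code{comp_id}. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken by first occurrence). An absent
#' \code{comp_id} yields an empty list, not an error.
#'
#' @param source file path or text (PDB records or CCD component CIF).
#' @param comp_id three-letter component code to extract.
#' @return list of \code{monomer_coords}, named \code{chain.resno}.
#' @export
read_monomer_coords <- function(source, comp_id) {
  is_path <- length(source) == 1 && !grepl("\n", source) && file.exists(source)
  text <- if (is_path) readLines(source, warn = FALSE) else
    if (length(source) == 1) strsplit(source, "\n", fixed = TRUE)[[1]] else source

  if (any(grepl("^(ATOM|HETATM)", text))) {
    pdbfile <- if (is_path) source else {
      tf <- tempfile(fileext = ".pdb")
      writeLines(text, tf)
      tf
    }
    pdb <- tryCatch(bio3d::read.pdb(pdbfile, verbose = FALSE, rm.alt = FALSE),
                    error = function(e) stop("cannot parse PDB input: ",
                                             conditionMessage(e)))
    at <- pdb$atom
    at <- at[trimws(at$resid) == comp_id, , drop = FALSE]
    if (!nrow(at)) return(list())
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                 sep = ".")
    out <- list()
    for (k in unique(key)) {
      res <- at[key == k, , drop = FALSE]
      # altloc: keep the highest-occupancy copy of each atom, tie -> first
      res$o[is.na(res$o)] <- 1
      ord <- order(trimws(res$elety), -res$o, seq_len(nrow(res)))
      res <- res[ord, , drop = FALSE]
      res <- res[!duplicated(trimws(res$elety)), , drop = FALSE]
      res <- res[order(match(trimws(res$elety), trimws(at$elety))), , drop = FALSE]
      m <- as.matrix(res[, c("x", "y", "z")])
      rownames(m) <- trimws(res$elety)
      out[[sub("\\.$", "", k)]] <- as_monomer_coords(m, occupancy = res$o)
    }
    return(out)
  }

  ## CCD-style component CIF
  blocks <- .cif_parse(text)
  out <- list()
  for (bn in names(blocks)) {
    at <- blocks[[bn]]$loops[["chem_comp_atom"]]
    if (is.null(at)) next
    ids <- if ("comp_id" %in% names(at)) trimws(at$comp_id) else
      rep(sub("^comp_", "", bn), nrow(at))
    at <- at[ids == comp_id, , drop = FALSE]
    if (!nrow(at)) next
    cols <- if (all(c("model_Cartn_x", "model_Cartn_y", "model_Cartn_z") %in% names(at)))
      c("model_Cartn_x", "model_Cartn_y", "model_Cartn_z")
    else if (all(c("x", "y", "z") %in% names(at))) c("x", "y", "z")
    else if (all(c("pdbx_model_Cartn_x_ideal", "pdbx_model_Cartn_y_ideal",
                   "pdbx_model_Cartn_z_ideal") %in% names(at)))
      c("pdbx_model_Cartn_x_ideal", "pdbx_model_Cartn_y_ideal",
        "pdbx_model_Cartn_z_ideal")
    else stop("component block '", bn, "' has no Cartesian coordinate columns")
    m <- vapply(cols, function(cn) .cif_num(at[[cn]]), numeric(nrow(at)))
    m <- matrix(m, ncol = 3)
    rownames(m) <- trimws(at$atom_id)
    out[[bn]] <- as_monomer_coords(m)
  }
  out
}
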