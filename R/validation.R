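## Per-sugar validation: anomeric configuration, chirality, puckering
## amplitude and ring conformation, combined into a yes/no/check verdict.
## "yes" means all four criteria pass; "check" means the ring conformation
## is the only failing criterion (a high-energy pucker that the user should
## verify against density); anything else is "no".

#' Default conformational expectations for common pyranoses
#'
#' The built-in expectation table covers the most frequently modelled
#' pyranosides. Saturated D-pyranoses are expected in the 4C1 chair and
#' L-pyranoses in the 1C4 chair; individual components can override the
#' rule (e.g. sialic acid).
#'
#' @param comp_id optional component code(s) to look up; unknown saturated
#'   components fall back to the series rule via \code{series}.
#' @param series fallback series ("D" or "L") for components missing from
#'   the table.
#' @return data frame with columns \code{comp_id}, \code{series},
#'   \code{expected_conformer}, \code{expected_anomer}, \code{saturated}.
#' @export
default_expectations <- function(comp_id = NULL, series = "D") {
  tab <- data.frame(
    comp_id = c("NAG", "MAN", "BMA", "GLC", "BGC",
                "BOG", "FUL", "GAL", "GLA", "SIA"),
    series = c("D", "D", "D", "D", "D", "D", "L", "D", "D", "D"),
    expected_conformer = c("4C1", "4C1", "4C1", "4C1", "4C1",
                           "4C1", "1C4", "4C1", "4C1", "1C4"),
    expected_anomer = c("beta", "alpha", "beta", "alpha", "beta",
                        "beta", "beta", "beta", "alpha", "alpha"),
    saturated = TRUE,
    stringsAsFactors = FALSE)
  if (is.null(comp_id)) return(tab)
  out <- tab[match(comp_id, tab$comp_id), , drop = FALSE]
  miss <- is.na(out$comp_id)
  if (any(miss)) {
    out$comp_id[miss] <- comp_id[miss]
    out$series[miss] <- series
    out$expected_conformer[miss] <- ifelse(series == "L", "1C4", "4C1")
    out$expected_anomer[miss] <- "beta"
    out$saturated[miss] <- TRUE
  }
  rownames(out) <- NULL
  out
}

#' Check chiral centres against their restraints
#'
#' For each chiral restraint the sign of the scalar triple product of the
#' three centre-to-neighbour vectors must match the restraint's sign
#' (\code{"both"} always passes). Missing atoms yield a violation of kind
#' \code{"incomplete"} rather than an error.
#'
#' @param coords \code{monomer_coords}.
#' @param d \code{\link{restraint_dictionary}} holding the chiral
#'   restraints.
#' @return data frame of violations (empty when all centres match) with
#'   columns \code{id}, \code{centre}, \code{kind} (\code{"sign"} or
#'   \code{"incomplete"}), \code{expected}, \code{observed},
#'   \code{volume}.
#' @export
check_chirality <- function(coords, d) {
  out <- data.frame(id = character(0), centre = character(0),
                    kind = character(0), expected = character(0),
                    observed = character(0), volume = numeric(0),
                    stringsAsFactors = FALSE)
  ch <- d$chiralities
  for (i in seq_len(nrow(ch))) {
    row <- ch[i, ]
    atoms <- c(row$centre, row$atom1, row$atom2, row$atom3)
    if (!all(atoms %in% rownames(coords))) {
      out <- rbind(out, data.frame(id = row$id, centre = row$centre,
                                   kind = "incomplete", expected = row$sign,
                                   observed = NA, volume = NA))
      next
    }
    xyz <- unclass(.coords_of(coords, atoms))
    v1 <- xyz[2, 1:3] - xyz[1, 1:3]
    v2 <- xyz[3, 1:3] - xyz[1, 1:3]
    v3 <- xyz[4, 1:3] - xyz[1, 1:3]
    vol <- sum(.cross(v1, v2) * v3)
    obs <- if (abs(vol) < 1e-6) "flat" else if (vol > 0) "positive" else "negative"
    if (row$sign == "both") next
    if (!identical(obs, row$sign))
      out <- rbind(out, data.frame(id = row$id, centre = row$centre,
                                   kind = "sign", expected = row$sign,
                                   observed = obs, volume = vol))
  }
  out
}

#' Check the anomeric configuration
#'
#' Determines the axial/equatorial disposition of the anomeric substituent
#' from the angle between the anomeric-carbon-to-substituent vector and the
#' Cremer-Pople mean-plane normal, and compares it with the disposition
#' expected for the component's series and anomer in the observed
#' conformation (in its home chair hemisphere an alpha anomer is axial and
#' a beta anomer equatorial for both series; in the inverted hemisphere the
#' disposition flips). Equatorial-band conformations (theta within 15
#' degrees of 90) and a missing anomeric substituent (e.g. a glycosidically
#' linked atom that is absent) give an indeterminate result, treated as a
#' pass with a warning detail.
#'
#' @param coords \code{monomer_coords}.
#' @param ring ring atom names from \code{\link{detect_ring}}.
#' @param d the component's \code{restraint_dictionary} (for connectivity).
#' @param expectation one row of an expectation table
#'   (\code{\link{default_expectations}}).
#' @return list with \code{pass}, \code{status} (\code{"pass"},
#'   \code{"fail"} or \code{"indeterminate"}) and \code{detail}.
#' @export
check_anomeric <- function(coords, ring, d, expectation) {
  anomeric <- attr(ring, "anomeric")
  if (is.null(anomeric)) anomeric <- ring[2]
  elem <- setNames(toupper(trimws(ifelse(is.na(d$atoms$element),
                                         substr(d$atoms$name, 1, 1),
                                         d$atoms$element))), d$atoms$name)
  nb <- unique(c(d$bonds$atom2[d$bonds$atom1 == anomeric],
                 d$bonds$atom1[d$bonds$atom2 == anomeric]))
  subs <- setdiff(nb[elem[nb] %in% c("O", "N")], ring)
  subs <- subs[subs %in% rownames(coords)]
  if (!length(subs))
    return(list(pass = TRUE, status = "indeterminate",
                detail = "anomeric substituent absent (possibly glycosidically linked)"))
  sub_atom <- subs[1]
  cp <- cremer_pople(coords, ring)
  if (cp$planar || abs(cp$theta - 90) < 15)
    return(list(pass = TRUE, status = "indeterminate",
                detail = sprintf("equatorial-band conformation (theta = %.1f): axial/equatorial undefined",
                                 if (cp$planar) NA else cp$theta)))
  v <- .unit(unclass(coords)[sub_atom, 1:3] - unclass(coords)[anomeric, 1:3])
  ang_to_normal <- .deg(acos(max(-1, min(1, abs(sum(v * cp$normal))))))
  observed <- if (ang_to_normal < 45) "axial" else "equatorial"
  home <- if (identical(expectation$series, "L")) cp$theta > 90 else cp$theta < 90
  expected_axial <- if (home) identical(expectation$expected_anomer, "alpha")
  else identical(expectation$expected_anomer, "beta")
  expected <- if (expected_axial) "axial" else "equatorial"
  list(pass = observed == expected,
       status = if (observed == expected) "pass" else "fail",
       detail = if (observed == expected)
         sprintf("%s substituent %s as expected for %s anomer", sub_atom,
                 observed, expectation$expected_anomer)
       else sprintf("wrong anomer: %s is %s but %s anomer expects %s",
                    sub_atom, observed, expectation$expected_anomer, expected))
}

## Verdict rule: yes iff all criteria pass; check iff conformation is the
## sole failure; no otherwise.
.verdict <- function(anomeric_ok, chirality_ok, amplitude_ok, conformation_ok) {
  if (anomeric_ok && chirality_ok && amplitude_ok && conformation_ok) "yes"
  else if (anomeric_ok && chirality_ok && amplitude_ok) "check"
  else "no"
}

#' Diagnose one sugar model
#'
#' Runs the four per-sugar checks (anomeric configuration, chirality,
#' puckering amplitude, ring conformation) and combines them: \code{"yes"}
#' when all pass, \code{"check"} when the ring conformation is the only
#' failure, \code{"no"} otherwise.
#'
#' @param coords \code{monomer_coords} of the sugar.
#' @param d its \code{restraint_dictionary}.
#' @param expectation one expectation row; defaults to the built-in table
#'   entry for \code{d$comp_id}.
#' @param q_window puckering-amplitude window (Angstrom); default
#'   \code{c(0.35, 0.9)}, bracketing typical chair amplitudes
#'   (~0.55-0.63 A).
#' @return object of class \code{sugar_diagnosis}: \code{verdict},
#'   \code{reasons} (per-criterion data frame), \code{pucker},
#'   \code{label}.
#' @export
diagnose <- function(coords, d, expectation = NULL,
                     q_window = c(0.35, 0.9)) {
  if (is.null(expectation))
    expectation <- default_expectations(d$comp_id)[1, ]
  ring <- detect_ring(d)
  missing <- setdiff(ring, rownames(coords))
  if (length(missing))
    stop("coordinates lack ring atom(s): ", paste(missing, collapse = ", "))
  cp <- cremer_pople(coords, ring)
  label <- classify_conformer(cp)

  anom <- check_anomeric(coords, ring, d, expectation)
  chir <- check_chirality(coords, d)
  chir_ok <- nrow(chir) == 0
  amp_ok <- !cp$planar && cp$Q >= q_window[1] && cp$Q <= q_window[2]
  conf_ok <- !is_high_energy(label, expectation$expected_conformer)

  reasons <- data.frame(
    criterion = c("anomeric", "chirality", "amplitude", "conformation"),
    pass = c(anom$pass, chir_ok, amp_ok, conf_ok),
    detail = c(anom$detail,
               if (chir_ok) "all chiral centres match"
               else paste("violations at:", paste(unique(chir$centre), collapse = ", ")),
               sprintf("Q = %.3f A (window %.2f-%.2f)", cp$Q,
                       q_window[1], q_window[2]),
               sprintf("observed %s, expected %s", label$name,
                       expectation$expected_conformer)),
    stringsAsFactors = FALSE)

  structure(list(
    verdict = .verdict(anom$pass, chir_ok, amp_ok, conf_ok),
    reasons = reasons, pucker = cp, label = label,
    comp_id = d$comp_id, expectation = expectation),
    class = "sugar_diagnosis")
}

#' @export
print.sugar_diagnosis <- function(x, ...) {
  cat(sprintf("%s: verdict '%s' (%s, Q = %.3f A, theta = %s, phi = %s)\n",
              x$comp_id, x$verdict, x$label$name, x$pucker$Q,
              if (is.na(x$pucker$theta)) "NA" else sprintf("%.1f", x$pucker$theta),
              if (is.na(x$pucker$phi)) "NA" else sprintf("%.1f", x$pucker$phi)))
  for (i in seq_len(nrow(x$reasons)))
    cat(sprintf("  [%s] %-12s %s\n",
                if (x$reasons$pass[i]) "ok" else "FAIL",
                x$reasons$criterion[i], x$reasons$detail[i]))
  invisible(x)
}

#' Batch validation report
#'
#' Diagnoses a collection of sugar models and tabulates per-verdict counts,
#' optionally stratified into three equal-count resolution bins.
#'
#' @param models list of \code{monomer_coords}.
#' @param dictionaries either one \code{restraint_dictionary} for all
#'   models or a named list keyed by component id.
#' @param expectations expectation table as from
#'   \code{\link{default_expectations}}; defaults to the built-in table.
#' @param comp_ids component id per model; defaults to
#'   \code{names(models)} stripped of instance suffixes, else the single
#'   dictionary's id.
#' @param resolution optional numeric vector (Angstrom), one per model.
#' @param q_window passed to \code{\link{diagnose}}.
#' @return object of class \code{sugar_report}: \code{counts} (named
#'   yes/no/check), \code{per_sugar} data frame and, when resolutions are
#'   supplied, \code{by_resolution}.
#' @export
batch_report <- function(models, dictionaries, expectations = NULL,
                         comp_ids = NULL, resolution = NULL,
                         q_window = c(0.35, 0.9)) {
  n <- length(models)
  single_dict <- inherits(dictionaries, "restraint_dictionary")
  if (is.null(comp_ids)) {
    comp_ids <- if (single_dict) rep(dictionaries$comp_id, n)
    else sub("[._-].*$", "", names(models))
  }
  rows <- list()
  for (i in seq_len(n)) {
    d <- if (single_dict) dictionaries else dictionaries[[comp_ids[i]]]
    if (is.null(d)) stop("no dictionary for component ", comp_ids[i])
    ex <- if (is.null(expectations)) default_expectations(comp_ids[i])[1, ]
    else expectations[match(comp_ids[i], expectations$comp_id), , drop = FALSE]
    dg <- diagnose(models[[i]], d, ex, q_window = q_window)
    rows[[i]] <- data.frame(
      id = if (!is.null(names(models))) names(models)[i] else as.character(i),
      comp_id = comp_ids[i], verdict = dg$verdict,
      Q = dg$pucker$Q, theta = dg$pucker$theta, phi = dg$pucker$phi,
      conformer = dg$label$name,
      resolution = if (is.null(resolution)) NA_real_ else resolution[i],
      stringsAsFactors = FALSE)
  }
  per_sugar <- if (n) do.call(rbind, rows) else
    data.frame(id = character(0), comp_id = character(0),
               verdict = character(0), Q = numeric(0), theta = numeric(0),
               phi = numeric(0), conformer = character(0),
               resolution = numeric(0), stringsAsFactors = FALSE)
  counts <- c(yes = sum(per_sugar$verdict == "yes"),
              no = sum(per_sugar$verdict == "no"),
              check = sum(per_sugar$verdict == "check"))
  by_res <- NULL
  if (!is.null(resolution) && n >= 3) {
    ## three equal-count bins
    qs <- stats::quantile(resolution, c(1 / 3, 2 / 3), type = 1)
    bin <- cut(resolution, c(-Inf, qs, Inf),
               labels = c("high", "medium", "low"))
    by_res <- as.data.frame.matrix(table(bin, per_sugar$verdict))
  }
  structure(list(counts = counts, per_sugar = per_sugar,
                 by_resolution = by_res), class = "sugar_report")
}

#' @export
print.sugar_report <- function(x, ...) {
  cat(sprintf("sugar_report: %d sugars (yes %d / check %d / no %d)\n",
              nrow(x$per_sugar), x$counts["yes"], x$counts["check"],
              x$counts["no"]))
  if (!is.null(x$by_resolution)) {
    cat("by resolution bin:\n")
    print(x$by_resolution)
  }
  invisible(x)
}

#' Theta-phi scatter of a validation report
#'
#' Plots classified sugars on the (phi, theta) rectangle with the verdict
#' as colour, mirroring the conformational-analysis scatter used when
#' monitoring chair-to-boat transitions.
#'
#' @param x a \code{sugar_report}.
#' @param ... passed to \code{plot}.
#' @export
plot.sugar_report <- function(x, ...) {
  ps <- x$per_sugar
  col <- c(yes = "forestgreen", check = "orange", no = "red")[ps$verdict]
  graphics::plot(ps$phi, ps$theta, col = col, pch = 19,
                 xlim = c(0, 360), ylim = c(180, 0),
                 xlab = expression(phi ~ "(deg)"),
                 ylab = expression(theta ~ "(deg)"), ...)
  graphics::legend("topright", legend = c("yes", "check", "no"),
                   col = c("forestgreen", "orange", "red"), pch = 19, bty = "n")
  invisible(x)
}

#' Write a per-sugar validation table
#'
#' @param report a \code{sugar_report}.
#' @param path output path for the tab-separated table.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$per_sugar, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
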