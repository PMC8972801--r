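test_that("ring detection finds and orients the pyranose ring", {
  fx <- make_sugar("D", "4C1", "beta", "NAG")
  ring <- detect_ring(fx$dictionary)
  expect_identical(as.character(ring), c("O5", "C1", "C2", "C3", "C4", "C5"))
  expect_identical(attr(ring, "anomeric"), "C1")
})

test_that("a ketopyranose ring is oriented by the anomeric-carbon rule", {
  # sialic-acid-like connectivity: ring O6-C2..C6, anomeric C2 carries two
  # oxygens (O2 hydroxyl and the C1 carboxylate is carbon, so O2 only) plus
  # exocyclic O at C4; give C2 a second oxygen to exercise the max rule
  atoms <- data.frame(
    name = c("O6", "C2", "C3", "C4", "C5", "C6", "O2", "O2B", "O4", "C7"),
    element = c("O", "C", "C", "C", "C", "C", "O", "O", "O", "C"),
    charge = 0, stringsAsFactors = FALSE)
  bonds <- data.frame(
    atom1 = c("O6", "C2", "C3", "C4", "C5", "C6", "C2", "C2", "C4", "C6"),
    atom2 = c("C2", "C3", "C4", "C5", "C6", "O6", "O2", "O2B", "O4", "C7"),
    order = "single", value = 1.5, sigma = 0.02, stringsAsFactors = FALSE)
  d <- restraint_dictionary("SIA", comp_type = "ketopyranose",
                            atoms = atoms, bonds = bonds)
  ring <- detect_ring(d)
  expect_identical(as.character(ring),
                   c("O6", "C2", "C3", "C4", "C5", "C6"))
  expect_identical(attr(ring, "anomeric"), "C2")
})

test_that("an open-chain molecule is rejected as not a pyranose", {
  atoms <- data.frame(name = c("C1", "C2", "C3", "O1"),
                      element = c("C", "C", "C", "O"), charge = 0,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(atom1 = c("C1", "C2", "C3"),
                      atom2 = c("C2", "C3", "O1"), order = "single",
                      value = 1.5, sigma = 0.02, stringsAsFactors = FALSE)
  d <- restraint_dictionary("LIN", atoms = atoms, bonds = bonds)
  expect_error(detect_ring(d), "not a pyranose")
})

test_that("dihedral follows the IUPAC convention on constructed cases", {
  p1 <- c(1.5, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1.5)
  cis <- p3 + 1.5 * c(sin(.5 * pi - (109.47 - 90) * pi / 180), 0,
                      cos(.5 * pi - (109.47 - 90) * pi / 180))
  # place the cis atom exactly: in the p1-p2-p3 plane, same side as p1
  cis <- p3 + 1.5 * c(sin((180 - 109.47) * pi / 180), 0,
                      cos((180 - 109.47) * pi / 180))
  expect_equal(dihedral_angle(p1, p2, p3, cis), 0, tolerance = 1e-12)
  trans <- p3 + 1.5 * c(-sin((180 - 109.47) * pi / 180), 0,
                        cos((180 - 109.47) * pi / 180))
  expect_equal(abs(dihedral_angle(p1, p2, p3, trans)), 180, tolerance = 1e-9)

  # axis-angle construction is the oracle: rotating the cis position by
  # +60 about the p2->p3 axis must measure 60
  p4 <- sugarpucker:::rotate_about_axis(cis, p3, p3 - p2, 60)
  expect_equal(dihedral_angle(p1, p2, p3, p4), 60, tolerance = 1e-9)

  # the IUPAC torsion is invariant under reversing the atom order and
  # negates under mirror inversion
  set.seed(7)
  for (i in 1:20) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    a <- tryCatch(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                  error = function(e) NA)
    if (is.na(a) || abs(abs(a) - 180) < 1e-9) next
    expect_equal(dihedral_angle(q[4, ], q[3, ], q[2, ], q[1, ]), a,
                 tolerance = 1e-9)
    qm <- q; qm[, 1] <- -qm[, 1]
    expect_equal(dihedral_angle(qm[1, ], qm[2, ], qm[3, ], qm[4, ]), -a,
                 tolerance = 1e-9)
  }
})

test_that("collinear points give an undefined-torsion error", {
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("ring torsions: planar ring is all zero, chair alternates sign", {
  flat <- hexagon_with_z(rep(0, 6))
  expect_equal(unname(ring_torsions(flat, rownames(flat))), rep(0, 6),
               tolerance = 1e-9)
  chair <- build_ring(0.55, 0, 0)
  tt <- unname(ring_torsions(chair, rownames(chair)))
  expect_true(all(abs(tt) > 40) && all(abs(tt) < 65))
  expect_equal(abs(diff(sign(tt))), rep(2, 5))   # alternating signs
  expect_gt(tt[2], 0)   # O5-C1-C2-C3 is positive in the 4C1 chair
  expect_equal(abs(tt), rep(abs(tt[1]), 6), tolerance = 1e-9)
})

test_that("ring torsions agree with an independent dihedral computation", {
  # bio3d's torsion.xyz is the independent oracle
  set.seed(11)
  for (rep in 1:5) {
    r <- build_ring(runif(1, 0.3, 0.8), runif(1, 0, 180), runif(1, 0, 360))
    ringnm <- rownames(r)
    mine <- ring_torsions(r, ringnm)
    idx <- function(k) ((k - 1) %% 6) + 1
    for (k in 1:6) {
      quad <- vapply(c(k - 1, k, k + 1, k + 2), function(q)
        ringnm[idx(q)], "")
      xyz <- as.numeric(t(unclass(r)[quad, 1:3]))
      oracle <- bio3d::torsion.xyz(xyz, atm.inc = 4)
      expect_equal(unname(mine[k]), unname(oracle[!is.na(oracle)][1]),
                   tolerance = 1e-6)
    }
  }
})

test_that("measurements are rigid-motion invariant and mirror-antisymmetric", {
  set.seed(13)
  r <- build_ring(0.55, 35, 120)
  base <- ring_torsions(r, rownames(r))
  for (i in 1:5) {
    R <- sugarpucker:::random_rotation()
    t <- rnorm(3, sd = 10)
    moved <- sugarpucker:::transform_coords(r, R, t)
    expect_equal(ring_torsions(moved, rownames(r)), base, tolerance = 1e-9)
  }
  mir <- unclass(r)[, 1:3]; mir[, 1] <- -mir[, 1]
  mirrored <- as_monomer_coords(mir)
  expect_equal(unname(ring_torsions(mirrored, rownames(r))), -unname(base),
               tolerance = 1e-9)
})
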