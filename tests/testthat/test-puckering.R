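test_that("alternating-displacement hexagons give the chair poles", {
  up <- hexagon_with_z(0.25 * c(1, -1, 1, -1, 1, -1))
  cp <- cremer_pople(up)
  expect_equal(cp$theta, 0, tolerance = 1e-6)
  expect_equal(cp$q2, 0, tolerance = 1e-9)
  down <- hexagon_with_z(0.25 * c(-1, 1, -1, 1, -1, 1))
  expect_equal(cremer_pople(down)$theta, 180, tolerance = 1e-6)
})

test_that("displacing the two para atoms 0 and 3 gives a pure boat", {
  boat <- hexagon_with_z(c(0.35, 0, 0, 0.35, 0, 0))
  cp <- cremer_pople(boat)
  expect_equal(cp$theta, 90, tolerance = 1e-6)
  expect_equal(cp$q3, 0, tolerance = 1e-12)
})

test_that("pucker coordinates satisfy their internal invariants", {
  set.seed(31)
  for (i in 1:25) {
    r <- build_ring(runif(1, 0.2, 0.9), runif(1, 0, 180), runif(1, 0, 360))
    cp <- cremer_pople(r, planarity_q = 0)
    expect_equal(cp$Q^2, cp$q2^2 + cp$q3^2, tolerance = 1e-9)
    expect_equal(sum(cp$z), 0, tolerance = 1e-9)
    j <- 0:5
    expect_equal(sum(cp$z * sin(2 * pi * j / 6)), 0, tolerance = 1e-9)
    expect_equal(sum(cp$z * cos(2 * pi * j / 6)), 0, tolerance = 1e-9)
    if (!cp$planar && cp$q2 > 1e-9)
      expect_equal(cp$theta, atan2(cp$q2, cp$q3) * 180 / pi,
                   tolerance = 1e-9)
  }
})

test_that("forward-inverse round trip recovers (Q, theta, phi) on a grid", {
  err <- 0
  for (Q in c(0.3, 0.55, 0.8))
    for (th in seq(0, 180, by = 30))
      for (ph in seq(0, 330, by = 30)) {
        cp <- cremer_pople(build_ring(Q, th, ph), planarity_q = 0)
        err <- max(err, abs(cp$Q - Q), abs(cp$theta - th))
        if (th > 1e-9 && th < 180 - 1e-9)
          err <- max(err, min(abs(cp$phi - ph), 360 - abs(cp$phi - ph)))
      }
  expect_lt(err, 1e-6)
})

test_that("pucker is rigid-motion invariant and mirrors to 180 - theta", {
  set.seed(37)
  r <- build_ring(0.6, 70, 200)
  base <- cremer_pople(r)
  for (i in 1:5) {
    moved <- sugarpucker:::transform_coords(r, sugarpucker:::random_rotation(),
                                            rnorm(3, sd = 5))
    cp <- cremer_pople(moved)
    expect_equal(cp$Q, base$Q, tolerance = 1e-9)
    expect_equal(cp$theta, base$theta, tolerance = 1e-9)
    expect_equal(cp$phi, base$phi, tolerance = 1e-7)
  }
  mir <- unclass(r)[, 1:3]; mir[, 3] <- -mir[, 3]
  cp <- cremer_pople(as_monomer_coords(mir))
  expect_equal(cp$theta, 180 - base$theta, tolerance = 1e-9)
})

test_that("chair torsion magnitude grows monotonically with Q", {
  mags <- vapply(seq(0.2, 0.8, by = 0.1), function(Q) {
    r <- build_ring(Q, 0, 0)
    mean(abs(ring_torsions(r, rownames(r))))
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("a nearly flat ring is reported planar, not an error", {
  cp <- cremer_pople(hexagon_with_z(rep(1e-4, 6) * c(1, -1, 1, -1, 1, -1)))
  expect_true(cp$planar)
  expect_true(is.na(cp$theta) && is.na(cp$phi))
  expect_identical(classify_conformer(cp)$name, "planar")
})

test_that("classification matches a brute-force nearest-canonical search", {
  tab <- conformer_table()
  expect_identical(nrow(tab), 38L)
  expect_identical(as.integer(table(tab$family)[c("chair", "boat",
                                                  "skew-boat", "envelope",
                                                  "half-chair")]),
                   c(2L, 6L, 6L, 12L, 12L))
  set.seed(41)
  n <- 1000
  u <- runif(n, -1, 1)
  th <- acos(u) * 180 / pi
  ph <- runif(n, 0, 360)
  arc <- function(t1, p1, t2, p2) {
    c0 <- cos(t1 * pi / 180) * cos(t2 * pi / 180) +
      sin(t1 * pi / 180) * sin(t2 * pi / 180) * cos((p1 - p2) * pi / 180)
    acos(pmax(-1, pmin(1, c0)))
  }
  ok <- logical(n)
  for (i in seq_len(n)) {
    d <- arc(th[i], ph[i], tab$theta, tab$phi)
    got <- classify_conformer(list(theta = th[i], phi = ph[i],
                                   planar = FALSE))$name
    # ties are resolved by family preference; accept any minimal-distance name
    minset <- tab$name[abs(d - min(d)) < 1e-12]
    ok[i] <- got %in% minset &&
      (length(minset) > 1 || got == tab$name[which.min(d)])
  }
  expect_true(all(ok))
})

test_that("known landmarks classify to their named conformers", {
  expect_identical(classify_conformer(list(theta = 2, phi = 123,
                                           planar = FALSE))$name, "4C1")
  expect_identical(classify_conformer(list(theta = 178, phi = 11,
                                           planar = FALSE))$name, "1C4")
  skew <- cremer_pople(build_ring(0.55, 90, 30), planarity_q = 0.1)
  expect_identical(classify_conformer(skew)$family, "skew-boat")
  expect_identical(classify_conformer(list(theta = 90, phi = 270,
                                           planar = FALSE))$name, "1S5")
  expect_identical(classify_conformer(list(theta = 90, phi = 150,
                                           planar = FALSE))$name, "2SO")
  expect_identical(classify_conformer(list(theta = 50.8, phi = 330,
                                           planar = FALSE))$name, "OH5")
})

test_that("is_high_energy flags departures from the expected conformer", {
  expect_false(is_high_energy("4C1", "4C1"))
  expect_true(is_high_energy("1S5", "4C1"))
  expect_true(is_high_energy("2SO", "4C1"))
})
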