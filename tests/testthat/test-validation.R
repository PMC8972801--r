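test_that("chirality checks match a brute-force signed-volume evaluation", {
  set.seed(51)
  fx <- make_sugar("D", "4C1", "beta", "GLC")
  expect_identical(nrow(check_chirality(fx$coords, fx$dictionary)), 0L)

  # mirror inversion violates every single-signed centre
  mir <- unclass(fx$coords)[, 1:3]; mir[, 1] <- -mir[, 1]
  v <- check_chirality(as_monomer_coords(mir), fx$dictionary)
  expect_identical(sort(unique(v$centre)),
                   sort(fx$dictionary$chiralities$centre))

  # randomized coordinates: agreement with direct evaluation
  for (rep in 1:10) {
    pm <- unclass(fx$coords)[, 1:3] + matrix(rnorm(36, sd = 0.3), ncol = 3)
    rownames(pm) <- rownames(fx$coords)
    got <- check_chirality(as_monomer_coords(pm), fx$dictionary)
    ch <- fx$dictionary$chiralities
    exp_viol <- vapply(seq_len(nrow(ch)), function(i) {
      a <- pm[ch$centre[i], ]
      m <- rbind(pm[ch$atom1[i], ] - a, pm[ch$atom2[i], ] - a,
                 pm[ch$atom3[i], ] - a)
      s <- if (det(m) > 0) "positive" else "negative"
      s != ch$sign[i]
    }, logical(1))
    expect_identical(sort(got$id), sort(ch$id[exp_viol]))
  }

  # a missing atom is an "incomplete" violation, not a crash
  partial <- fx$coords[setdiff(rownames(fx$coords), "O2"), , drop = FALSE]
  class(partial) <- class(fx$coords)
  v2 <- check_chirality(partial, fx$dictionary)
  expect_true("incomplete" %in% v2$kind)
})

test_that("anomeric check flags the wrong anomer and handles absence", {
  fx <- make_sugar("D", "4C1", "beta", "GLC")
  ring <- detect_ring(fx$dictionary)
  e_beta <- default_expectations("BGC")[1, ]   # beta-D, 4C1
  expect_identical(check_anomeric(fx$coords, ring, fx$dictionary,
                                  e_beta)$status, "pass")
  e_alpha <- default_expectations("GLC")[1, ]  # alpha-D
  res <- check_anomeric(fx$coords, ring, fx$dictionary, e_alpha)
  expect_identical(res$status, "fail")
  expect_match(res$detail, "wrong anomer")
  # without the anomeric substituent the check is indeterminate
  no_o1 <- fx$coords[setdiff(rownames(fx$coords), "O1"), , drop = FALSE]
  class(no_o1) <- class(fx$coords)
  expect_identical(check_anomeric(no_o1, ring, fx$dictionary,
                                  e_beta)$status, "indeterminate")
})

test_that("the verdict rule is the exact yes/no/check truth table", {
  for (a in c(TRUE, FALSE)) for (ch in c(TRUE, FALSE))
    for (am in c(TRUE, FALSE)) for (co in c(TRUE, FALSE)) {
      v <- sugarpucker:::.verdict(a, ch, am, co)
      expected <- if (a && ch && am && co) "yes"
      else if (a && ch && am) "check" else "no"
      expect_identical(v, expected)
    }
})

test_that("diagnose: correct chair is yes, boat-only is check, mirror is no", {
  fx <- make_sugar("D", "4C1", "beta", "NAG")
  expect_identical(diagnose(fx$coords, fx$dictionary)$verdict, "yes")

  boat <- distort_ring(fx$coords, theta = 90, phi = 120, fraction = 1,
                       ring = detect_ring(fx$dictionary))
  dgb <- diagnose(boat, fx$dictionary)
  expect_identical(dgb$verdict, "check")
  expect_identical(dgb$reasons$pass, c(TRUE, TRUE, TRUE, FALSE))

  mir <- unclass(fx$coords)[, 1:3]; mir[, 1] <- -mir[, 1]
  expect_identical(diagnose(as_monomer_coords(mir),
                            fx$dictionary)$verdict, "no")
})

test_that("rebuilding a yes fixture at the antipodal chair flips to check", {
  fx <- make_sugar("D", "4C1", "beta", "BGC")
  flipped <- distort_ring(fx$coords, theta = 180, phi = 0, fraction = 1,
                          ring = detect_ring(fx$dictionary))
  dg <- diagnose(flipped, fx$dictionary)
  expect_identical(dg$verdict, "check")
  expect_identical(dg$reasons$pass[dg$reasons$criterion == "conformation"],
                   FALSE)
  expect_true(all(dg$reasons$pass[dg$reasons$criterion != "conformation"]))
})

test_that("diagnose is invariant under rigid motion", {
  set.seed(61)
  fx <- make_sugar("D", "1S5", "beta", "MAN")
  base <- diagnose(fx$coords, fx$dictionary)
  for (i in 1:3) {
    moved <- sugarpucker:::transform_coords(
      fx$coords, sugarpucker:::random_rotation(), rnorm(3, sd = 8))
    dg <- diagnose(moved, fx$dictionary)
    expect_identical(dg$verdict, base$verdict)
    expect_identical(dg$label$name, base$label$name)
    expect_equal(dg$pucker$theta, base$pucker$theta, tolerance = 1e-9)
  }
})

test_that("batch report counts verdicts and bins by resolution", {
  fx_ok <- make_sugar("D", "4C1", "beta", "NAG")
  ring <- detect_ring(fx_ok$dictionary)
  models <- list()
  for (i in 1:6) models[[paste0("ok", i)]] <- fx_ok$coords
  for (i in 1:3)
    models[[paste0("boat", i)]] <-
      distort_ring(fx_ok$coords, theta = 90, phi = 60 * i, fraction = 1,
                   ring = ring)
  mir <- unclass(fx_ok$coords)[, 1:3]; mir[, 1] <- -mir[, 1]
  models$mirrored <- as_monomer_coords(mir)
  rep <- batch_report(models, fx_ok$dictionary,
                      comp_ids = rep("NAG", length(models)))
  expect_identical(unname(rep$counts[c("yes", "check", "no")]),
                   c(6L, 3L, 1L))

  # empty input gives an all-zero table
  rep0 <- batch_report(list(), fx_ok$dictionary, comp_ids = character(0))
  expect_identical(sum(rep0$counts), 0L)

  # nine sugars binned by resolution into three equal-count bins
  res <- c(1.2, 1.4, 1.6, 1.82, 1.85, 1.88, 1.92, 1.95, 1.99)
  rep9 <- batch_report(models[1:9], fx_ok$dictionary,
                       comp_ids = rep("NAG", 9), resolution = res)
  expect_identical(unname(rowSums(rep9$by_resolution)), rep(3, 3))
})
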