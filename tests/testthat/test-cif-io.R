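test_that("the patched-dialect fixture parses with exact torsion fields", {
  d <- read_dictionary(fig_dialect_cif())
  expect_identical(d$comp_id, "NAG")
  expect_identical(d$comp_type, "pyranose")
  r2 <- d$torsions[d$torsions$id == "ring_2", ]
  expect_identical(r2$value, 53.65)
  expect_identical(r2$sigma, 3.0)
  expect_identical(r2$period, 1L)
  expect_identical(unlist(r2[, paste0("atom", 1:4)], use.names = FALSE),
                   c("O5", "C1", "C2", "C3"))
  expect_identical(d$torsions$id[1:2], c("ring_1", "ring_2"))
})

test_that("missing optional loops yield empty tables, not errors", {
  txt <- fig_dialect_cif()
  cut <- grep("_chem_comp_tor.comp_id", txt, fixed = TRUE) - 1  # its loop_
  d <- read_dictionary(txt[seq_len(cut - 1)])
  expect_identical(nrow(d$torsions), 0L)
  expect_identical(nrow(d$chiralities), 0L)
  expect_identical(nrow(d$planes), 0L)
})

test_that("parsing is insensitive to loop column order and comments", {
  base <- read_dictionary(fig_dialect_cif())
  txt <- fig_dialect_cif()
  # swap the value/sigma columns of the torsion loop
  i_val <- grep("_chem_comp_tor.value_angle$", txt)
  i_esd <- grep("_chem_comp_tor.value_angle_esd", txt)
  txt[c(i_val, i_esd)] <- txt[c(i_esd, i_val)]
  rows <- grep("^NAG (ring|tors)", txt)
  for (i in rows) {
    f <- strsplit(txt[i], " +")[[1]]
    txt[i] <- paste(c(f[1:6], f[8], f[7], f[9]), collapse = " ")
  }
  txt <- append(txt, "# a comment line", after = 3)
  d <- read_dictionary(txt)
  expect_equal(d$torsions, base$torsions)
})

test_that("torsions referencing unknown atoms are an integrity error", {
  txt <- sub("NAG ring_2 O5 C1 C2 C3", "NAG ring_2 O5 C1 C2 C9",
             fig_dialect_cif(), fixed = TRUE)
  expect_error(read_dictionary(txt), "unknown atom")
})

test_that("a malformed loop is reported with the loop name", {
  txt <- c(fig_dialect_cif(), "NAG dangling")
  expect_error(read_dictionary(txt), "chem_comp_tor")
})

test_that("read-write round trip is the identity on all fields", {
  set.seed(101)
  for (rep in 1:20) {
    d <- random_dictionary()
    d2 <- read_dictionary(write_dictionary(d))
    expect_identical(d2$comp_id, d$comp_id)
    expect_identical(d2$comp_type, d$comp_type)
    expect_equal(d2$atoms$name, d$atoms$name)
    expect_equal(d2$bonds[, c("atom1", "atom2", "value", "sigma")],
                 d$bonds[, c("atom1", "atom2", "value", "sigma")])
    expect_equal(d2$torsions, d$torsions)
  }
})

test_that("write-read-write is byte-identical", {
  set.seed(202)
  d <- random_dictionary()
  t1 <- write_dictionary(d)
  t2 <- write_dictionary(read_dictionary(t1))
  expect_identical(t1, t2)
})

test_that("an empty torsion list writes a valid entry with no torsion loop", {
  fx <- make_ring_fixture()
  d <- fx$dictionary
  txt <- write_dictionary(d)
  expect_false(any(grepl("_chem_comp_tor", txt)))
  expect_identical(nrow(read_dictionary(txt)$torsions), 0L)
})

test_that("unknown loops are preserved through read and write", {
  txt <- c(fig_dialect_cif(),
           "loop_",
           "_custom_block.comp_id", "_custom_block.note",
           "NAG keepme", "NAG metoo")
  d <- read_dictionary(txt)
  expect_true("custom_block" %in% names(d$extra))
  out <- write_dictionary(d)
  expect_true(any(grepl("keepme", out)))
  d2 <- read_dictionary(out)
  expect_equal(d2$extra$custom_block$note, c("keepme", "metoo"))
})

test_that("PDB residues are extracted per chain with altlocs resolved", {
  fx <- make_sugar("D", "4C1", "beta", "NAG")
  txt <- sugar_pdb_text(list(fx$coords, fx$coords), "NAG", c("A", "B"))
  res <- read_monomer_coords(txt, "NAG")
  expect_length(res, 2)
  expect_identical(nrow(res[[1]]), nrow(fx$coords))
  expect_identical(length(read_monomer_coords(txt, "XYZ")), 0L)

  # altloc: B copy of O1 has the higher occupancy and must win
  one <- sugar_pdb_text(list(fx$coords), "NAG", "A")
  i_o1 <- grep(" O1 ", one)
  lineA <- sub("(.{16})(.)", "\\1A", one[i_o1])
  lineA <- sub("  1\\.00", "  0.40", lineA)
  shifted <- unclass(fx$coords)["O1", 1:3] + c(0.5, 0, 0)
  lineB <- sprintf(
    "HETATM%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    99, "O1", "B", "NAG", "A", 1, shifted[1], shifted[2], shifted[3],
    0.60, 20, "O")
  two <- append(one[-i_o1], c(lineA, lineB), after = i_o1 - 1)
  res2 <- read_monomer_coords(two, "NAG")
  expect_length(res2, 1)
  expect_equal(unname(unclass(res2[[1]])["O1", 1]),
               unname(round(shifted[1], 3)), tolerance = 1e-6)
})

test_that("CCD-style component blocks are read by comp_id", {
  fx <- make_ring_fixture()
  m <- unclass(fx$coords)[, 1:3]
  txt <- c("data_RNG",
           "loop_",
           "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
           "_chem_comp_atom.type_symbol",
           "_chem_comp_atom.model_Cartn_x", "_chem_comp_atom.model_Cartn_y",
           "_chem_comp_atom.model_Cartn_z",
           vapply(seq_len(nrow(m)), function(i)
             sprintf("RNG %s %s %.3f %.3f %.3f", rownames(m)[i],
                     substr(rownames(m)[i], 1, 1), m[i, 1], m[i, 2], m[i, 3]),
             ""))
  res <- read_monomer_coords(txt, "RNG")
  expect_length(res, 1)
  expect_equal(unclass(res[[1]])[, 1:3], round(m, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})
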