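# Shared fixture builders. Everything is generated in code; no binary data.

# Hexagon with prescribed out-of-plane displacements, vertex j at angle
# -60j deg so the Cremer-Pople mean-plane normal is +z.
hexagon_with_z <- function(z, radius = 1.45,
                           names = c("O5", "C1", "C2", "C3", "C4", "C5")) {
  j <- 0:5
  ang <- -2 * pi * j / 6
  m <- cbind(radius * cos(ang), radius * sin(ang), z)
  rownames(m) <- names
  as_monomer_coords(m)
}

# A small dictionary entry in the patched monomer-library dialect,
# including a ring_1 torsion with the 53.65-degree target.
fig_dialect_cif <- function() {
  c("# synthetic NAG-like entry, patched dialect",
    "data_comp_list",
    "loop_",
    "_chem_comp.id", "_chem_comp.three_letter_code", "_chem_comp.name",
    "_chem_comp.group", "_chem_comp.number_atoms_all",
    "_chem_comp.number_atoms_nh", "_chem_comp.desc_level",
    'NAG NAG "2-acetamido-2-deoxy-beta-D-glucopyranose" pyranose 8 8 .',
    "",
    "data_comp_NAG",
    "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol", "_chem_comp_atom.charge",
    "NAG O5 O 0.000", "NAG C1 C 0.000", "NAG C2 C 0.000", "NAG C3 C 0.000",
    "NAG C4 C 0.000", "NAG C5 C 0.000", "NAG O1 O 0.000", "NAG N2 N 0.000",
    "loop_",
    "_chem_comp_bond.comp_id", "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2", "_chem_comp_bond.type",
    "_chem_comp_bond.value_dist", "_chem_comp_bond.value_dist_esd",
    "NAG O5 C1 single 1.426 0.011", "NAG C1 C2 single 1.525 0.013",
    "NAG C2 C3 single 1.525 0.013", "NAG C3 C4 single 1.523 0.013",
    "NAG C4 C5 single 1.528 0.013", "NAG C5 O5 single 1.436 0.011",
    "NAG C1 O1 single 1.423 0.012", "NAG C2 N2 single 1.455 0.012",
    "loop_",
    "_chem_comp_tor.comp_id", "_chem_comp_tor.id",
    "_chem_comp_tor.atom_id_1", "_chem_comp_tor.atom_id_2",
    "_chem_comp_tor.atom_id_3", "_chem_comp_tor.atom_id_4",
    "_chem_comp_tor.value_angle", "_chem_comp_tor.value_angle_esd",
    "_chem_comp_tor.period",
    "NAG ring_1 C5 O5 C1 C2 -55.100 3.000 1",
    "NAG ring_2 O5 C1 C2 C3 53.650 3.000 1",
    "NAG tors_1 O1 C1 C2 N2 180.000 10.000 3")
}

# Random small dictionary for round-trip property tests (values at <= 3
# decimals, the writer's fixed precision).
random_dictionary <- function() {
  n_at <- sample(6:10, 1)
  atoms <- data.frame(name = paste0(sample(c("C", "O", "N"), n_at, TRUE),
                                    seq_len(n_at)),
                      element = NA, charge = 0, stringsAsFactors = FALSE)
  atoms$element <- substr(atoms$name, 1, 1)
  # chain connectivity plus a couple of random extra bonds
  b1 <- atoms$name[-n_at]; b2 <- atoms$name[-1]
  bonds <- data.frame(atom1 = b1, atom2 = b2, order = "single",
                      value = round(runif(n_at - 1, 1.2, 1.6), 3),
                      sigma = round(runif(n_at - 1, 0.01, 0.02), 3),
                      stringsAsFactors = FALSE)
  n_t <- sample(0:4, 1)
  torsions <- if (n_t) {
    idx <- replicate(n_t, sample(n_at, 4))
    data.frame(id = paste0("var_", seq_len(n_t)),
               atom1 = atoms$name[idx[1, ]], atom2 = atoms$name[idx[2, ]],
               atom3 = atoms$name[idx[3, ]], atom4 = atoms$name[idx[4, ]],
               value = round(runif(n_t, -180, 180), 3),
               sigma = round(runif(n_t, 1, 20), 3),
               period = sample(c(1L, 2L, 3L, 6L), n_t, TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  restraint_dictionary(
    comp_id = paste0(sample(LETTERS, 3), collapse = ""),
    comp_name = "random fixture",
    comp_type = sample(c("pyranose", "ketopyranose", "non-polymer"), 1),
    atoms = atoms, bonds = bonds, torsions = torsions)
}

# Minimal PDB text with one or more copies of a sugar.
sugar_pdb_text <- function(coords_list, comp_id = "NAG",
                           chains = LETTERS[seq_along(coords_list)]) {
  serial <- 0
  out <- character(0)
  for (k in seq_along(coords_list)) {
    m <- unclass(coords_list[[k]])[, 1:3, drop = FALSE]
    for (i in seq_len(nrow(m))) {
      serial <- serial + 1
      out <- c(out, sprintf(
        "HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, rownames(m)[i], comp_id, chains[k], 1,
        m[i, 1], m[i, 2], m[i, 3], 1, 20, substr(rownames(m)[i], 1, 1)))
    }
  }
  c(out, "END")
}
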