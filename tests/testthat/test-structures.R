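test_that("PDB write/read round-trips coordinates, cell and chains", {
  cry <- toy_crystal()
  f <- tempfile(fileext = ".pdb")
  write_model(cry, f)
  back <- read_structure(f)
  a0 <- as_atoms(cry); a1 <- as_atoms(back)
  expect_equal(nrow(a0), nrow(a1))
  expect_equal(a0$chain, a1$chain)
  expect_equal(a0$resno, a1$resno)
  expect_equal(a0$atom, a1$atom)
  expect_lt(max(abs(atom_xyz(a0) - atom_xyz(a1))), 1e-3 + 1e-9)
  expect_equal(unname(back$cell), unname(cry$cell))
  expect_equal(back$spacegroup, "P 1")
})

test_that("multi-model PDB round-trips as a trajectory", {
  tr <- make_trajectory(toy_lattice_spec(bend = -10, noise = 0.1,
                                         n_snapshots = 3))
  f <- tempfile(fileext = ".pdb")
  write_model(tr, f)
  # a trajectory has no cell, so the reader warns about the missing CRYST1
  expect_warning(st <- read_structure(f), "CRYST1")
  back <- as_trajectory(st, dt_ps = tr$dt_ps)
  expect_equal(length(back$coords), 3)
  expect_lt(max(abs(back$coords[[3]] - tr$coords[[3]])), 1e-3 + 1e-9)
  expect_equal(length(unique(back$atoms$chain)), 18)
})

test_that("mmCIF parsing recovers atoms, cell and symmetry", {
  cif <- c("data_toy",
    "_cell.length_a 68.5", "_cell.length_b 68.5", "_cell.length_c 200.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0",
    "_cell.angle_gamma 120.0",
    "_symmetry.space_group_name_H-M \"P 6\"",
    "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . LYS A 1 26 ? 30.250 0.000 0.000 1.00 10.00 ? 26 LYS A N 1",
    "ATOM 2 C CA . LYS A 1 26 ? 31.250 0.500 0.000 1.00 10.00 ? 26 LYS A CA 1",
    "#")
  f <- tempfile(fileext = ".cif")
  writeLines(cif, f)
  b <- read_structure(f, format = "mmcif")
  a <- as_atoms(b)
  expect_equal(nrow(a), 2)
  expect_equal(a$resname[1], "LYS")
  expect_equal(length(b$sym_ops), 6)
  expect_equal(b$cell[["gamma"]], 120)
})

test_that("spacegroup operator tables have the right sizes", {
  expect_equal(length(bmchex:::spacegroup_ops("P 1")), 1)
  expect_equal(length(bmchex:::spacegroup_ops("P 6")), 6)
  expect_equal(length(bmchex:::spacegroup_ops("P 63")), 6)
  expect_equal(length(bmchex:::spacegroup_ops("P 6 2 2")), 12)
  expect_equal(length(bmchex:::spacegroup_ops("nonsense")), 0)
  # the 6-fold has order 6
  ops <- bmchex:::spacegroup_ops("P 6")
  g <- ops[[2]]$R
  acc <- diag(3)
  for (i in 1:6) acc <- g %*% acc
  expect_equal(acc, diag(3), tolerance = 1e-12)
})

test_that("orthogonalization matrix matches hexagonal geometry", {
  M <- orthogonalization_matrix(c(a = 10, b = 10, c = 20, alpha = 90,
                                  beta = 90, gamma = 120))
  # b axis at 120 degrees from a
  expect_equal(as.numeric(M %*% c(0, 1, 0)), c(-5, 5 * sqrt(3), 0),
               tolerance = 1e-12)
  expect_equal(as.numeric(M %*% c(0, 0, 1)), c(0, 0, 20), tolerance = 1e-12)
})

test_that("read_structure errors and warns usefully", {
  expect_error(read_structure("/no/such/file.pdb"), "not found")
  h <- make_toy_hexamer()
  f <- tempfile(fileext = ".pdb")
  write_model(h, f)                       # no cell on a bare hexamer
  expect_warning(read_structure(f), "CRYST1")
})
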