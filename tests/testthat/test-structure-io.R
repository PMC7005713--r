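test_that("fixture writer round-trips through the reader", {
  atoms <- build_his_residue(-60)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(atoms, path, ph = 6.2)
  s <- read_structure(path)
  expect_s3_class(s, "structure_model")
  expect_equal(nrow(s$atoms), nrow(atoms))
  expect_equal(s$atoms$x, atoms$x, tolerance = 1e-3)
  expect_equal(s$atoms$y, atoms$y, tolerance = 1e-3)
  expect_equal(s$atoms$z, atoms$z, tolerance = 1e-3)
  expect_identical(s$atoms$altloc, atoms$altloc)
  expect_equal(s$atoms$occupancy, atoms$occupancy)
  expect_identical(s$atoms$atom_name, atoms$atom_name)
  expect_equal(s$metadata$crystallization_ph, 6.2)
  # the His side chain is complete and measurable after the round trip
  res <- select_residue(s, "A", 260, require_resname = "HIS")
  ang <- chi1_angles(res)
  expect_true(ang$complete)
  expect_equal(ang$chi1, -60, tolerance = 1e-3)
})

test_that("alternate conformers are preserved and grouped", {
  path <- withr::local_tempfile(fileext = ".pdb")
  build_structure(list(A = c(-60, 170)), ph = 7, path = path)
  s <- read_structure(path)
  res <- select_residue(s, "A", 260)
  expect_setequal(unique(res$altloc), c("", "A", "B"))
  ang <- chi1_angles(res)
  expect_equal(nrow(ang), 2)
  expect_equal(sort(ang$chi1), c(-60, 170), tolerance = 1e-3)
  expect_equal(ang$occupancy, c(0.5, 0.5))
})

test_that("REMARK 280 pH parsing handles values, ranges and absence", {
  mk <- function(remark) {
    path <- tempfile(fileext = ".pdb")
    writeLines(c(remark,
                 paste0("ATOM      1  N   HIS A 260      11.104   6.134",
                        "  -6.504  1.00  0.00           N"),
                 "END"), path)
    path
  }
  p1 <- extract_crystal_ph(mk("REMARK 280  0.1 M TRIS-HCL PH 8.5"), "pdb")
  expect_equal(p1$crystallization_ph, 8.5)
  # a range becomes its midpoint with the range recorded
  p2 <- extract_crystal_ph(mk("REMARK 280 NA FORMATE, PH 7.6-8.6"), "pdb")
  expect_equal(p2$crystallization_ph, 8.1)
  expect_equal(p2$ph_range, "7.6-8.6")
  # no pH token -> missing, never a default
  p3 <- extract_crystal_ph(mk("REMARK 280 30% MPD, 0.02 M CACL2"), "pdb")
  expect_true(is.na(p3$crystallization_ph))
  # 'PHOSPHATE' must not be mistaken for a pH token
  p4 <- extract_crystal_ph(mk("REMARK 280 1.2 M NA/K PHOSPHATE"), "pdb")
  expect_true(is.na(p4$crystallization_ph))
  # out-of-scale numbers are rejected as missing, with a warning
  expect_warning(
    p5 <- extract_crystal_ph(mk("REMARK 280 BUFFER PH 85"), "pdb"),
    "outside"
  )
  expect_true(is.na(p5$crystallization_ph))
})

test_that("mmCIF parsing reads atoms, altlocs and crystal-growth pH", {
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_SYN1",
    "_exptl_crystal_grow.method       'VAPOR DIFFUSION'",
    "_exptl_crystal_grow.pH           5.6",
    "_exptl_crystal_grow.pdbx_details '1.7 M ammonium sulfate'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . HIS A 1 1 ? 11.104 6.134 -6.504 1.00 20.0 ? 260 HIS A N 1",
    "ATOM 2 C CA . HIS A 1 1 ? 12.560 6.351 -6.510 1.00 20.0 ? 260 HIS A CA 1",
    "ATOM 3 C CB A HIS A 1 1 ? 13.000 7.000 -7.800 0.60 20.0 ? 260 HIS A CB 1",
    "ATOM 4 C CG . HIS A 1 1 ? 14.400 7.500 -7.900 1.00 20.0 ? 260 HIS A CG 1"
  ), path)
  s <- read_structure(path, format = "mmcif")
  expect_equal(nrow(s$atoms), 4)
  expect_equal(s$metadata$crystallization_ph, 5.6)
  expect_equal(s$metadata$pdb_id, "SYN1")
  expect_true("A" %in% s$atoms$altloc)
  # author numbering is the addressing scheme
  expect_equal(unique(s$atoms$residue_number), 260)
})

test_that("selection errors are informative and missing files fail cleanly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  build_structure(list(A = -60), ph = 7, path = path)
  s <- read_structure(path)
  expect_error(select_residue(s, "Z", 260), "available chains")
  expect_error(select_residue(s, "A", 999), "not found")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
  # zero-atom file
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK 280 NOTHING", "END"), empty)
  expect_error(read_structure(empty), ".")
})

test_that("HETATM sulfate and its geometry survive the round trip", {
  path <- withr::local_tempfile(fileext = ".pdb")
  build_structure(list(A = -60), ph = 7.5, path = path,
                  sulfate = list(chain = "A", distance = 3.2))
  s <- read_structure(path)
  so4 <- s$atoms[s$atoms$residue_name == "SO4", ]
  expect_equal(nrow(so4), 5)
  expect_true(all(so4$record_type == "HETATM"))
  ne2 <- s$atoms[s$atoms$atom_name == "NE2" & s$atoms$chain_id == "A", ]
  d <- sqrt((so4$x - ne2$x)^2 + (so4$y - ne2$y)^2 + (so4$z - ne2$z)^2)
  expect_equal(min(d), 3.2, tolerance = 1e-3)
})
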