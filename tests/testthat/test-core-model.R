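# Structure I/O and container invariants.

make_benzene_sdf <- function(path) {
  ang <- (0:5) * pi / 3
  atoms <- c(
    sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
            1.395 * cos(ang), 1.395 * sin(ang), 0),
    sprintf("%10.4f%10.4f%10.4f H   0  0  0  0  0  0  0  0  0  0  0  0",
            2.475 * cos(ang), 2.475 * sin(ang), 0))
  bonds <- c(sprintf("%3d%3d  4  0", 1:6, c(2:6, 1)),
             sprintf("%3d%3d  1  0", 1:6, 7:12))
  writeLines(c("benzene", "  test", "",
               " 12 12  0  0  0  0  0  0  0  0999 V2000",
               atoms, bonds, "M  END", "$$$$"), path)
  path
}

make_ethylammonium_sdf <- function(path) {
  xyz <- rbind(c(0, 0, 0), c(1.47, 0, 0), c(2.0, 1.4, 0),
               c(-0.4, -0.9, 0.2), c(-0.4, 0.45, -0.8), c(-0.4, 0.55, 0.75),
               c(1.8, -0.55, 0.88), c(1.8, -0.5, -0.92),
               c(3.09, 1.39, 0), c(1.65, 1.93, 0.89), c(1.65, 1.98, -0.86))
  el <- c("N", "C", "C", rep("H", 8))
  bonds <- rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                 c(2, 7), c(2, 8), c(3, 9), c(3, 10), c(3, 11))
  writeLines(c("ethylammonium", "  test", "",
               " 11 10  0  0  0  0  0  0  0  0999 V2000",
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], el),
               sprintf("%3d%3d  1  0", bonds[, 1], bonds[, 2]),
               "M  CHG  1   1   1", "M  END", "$$$$"), path)
  path
}

test_that("multi-model PDB round trip preserves counts, numbering and coordinates", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 2, seed = 4)
  expect_equal(n_frames(ens), 2)
  expect_equal(n_residues(ens), 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  ens2 <- read_ensemble(path)
  expect_equal(n_frames(ens2), 2)
  expect_equal(n_residues(ens2), 3)
  for (f in 1:2)
    expect_equal(ens2$coords[[f]], ens$coords[[f]], tolerance = 1e-3)
  expect_identical(ens2$atoms$pdb_number, ens$atoms$pdb_number)
  expect_identical(ens2$atoms$atom_name, ens$atoms$atom_name)
  expect_identical(ens2$atoms$formal_charge, ens$atoms$formal_charge)
})

test_that("a model missing one atom is rejected naming the offending model", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  starts <- grep("^MODEL", lines)
  # drop the first atom of model 2
  bad <- atom_lines[atom_lines > starts[2]][1]
  writeLines(lines[-bad], path)
  expect_error(read_ensemble(path), "model 2")
  expect_error(read_ensemble(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("shared-topology and uniqueness invariants are enforced", {
  ens <- generate_peptide_ensemble(n_res = 3, n_frames = 2, seed = 4)
  expect_error(
    conformation_ensemble(ens$atoms, list(ens$coords[[1]][-1, ])),
    "do not match")
  expect_error(
    conformation_ensemble(ens$atoms, ens$coords, frame_ids = c(1, 1)),
    "unique")
  expect_error(conformation_ensemble(ens$atoms, list()), "at least one")
})

test_that("benzene SDF yields one 6-atom aromatic ring and net charge 0", {
  path <- make_benzene_sdf(withr::local_tempfile(fileext = ".sdf"))
  lig <- read_ligand(path)
  expect_equal(length(lig$aromatic_rings), 1)
  expect_equal(sort(lig$aromatic_rings[[1]]), 1:6)
  expect_equal(lig$net_charge, 0L)
  expect_equal(sum(lig$atoms$is_heavy), 6)
  expect_equal(nrow(lig$donors), 0)  # C-H hydrogens are not donors
})

test_that("ethylammonium SDF carries the N+ charge and one donor per N-H", {
  path <- make_ethylammonium_sdf(withr::local_tempfile(fileext = ".sdf"))
  lig <- read_ligand(path)
  expect_equal(lig$atoms$formal_charge[1], 1L)
  expect_equal(lig$net_charge, 1L)
  expect_equal(nrow(lig$donors), 3)          # three N-H groups
  expect_true(all(lig$donors[, 1] == 1L))
  expect_equal(length(lig$aromatic_rings), 0)
})

test_that("a hydrogen-free ligand warns and has no donors", {
  # ethane skeleton with its hydrogens stripped
  writeLines(c("ethane_noH", "  test", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
                       c(0, 1.54), c(0, 0), c(0, 0)),
               "  1  2  1  0",
               "M  END", "$$$$"),
             path <- withr::local_tempfile(fileext = ".sdf"))
  expect_warning(lig <- read_ligand(path), "no explicit hydrogens")
  expect_equal(nrow(lig$donors), 0)
  expect_equal(length(lig$acceptors), 0)
  expect_equal(length(lig$aromatic_rings), 0)
})

test_that("ligand SDF writing round-trips coordinates and charges", {
  lig <- generate_ligand(ring = TRUE, amine = TRUE, n_heavy = 8)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(lig, path)
  lig2 <- read_ligand(path)
  expect_equal(lig2$coords, lig$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(lig2$net_charge, lig$net_charge)
  expect_equal(length(lig2$aromatic_rings), 1)
})

test_that("ligand model invariants reject malformed inputs", {
  atoms <- data.frame(name = c("C1", "H2"), element = c("C", "H"),
                      formal_charge = c(0L, 0L))
  bonds <- data.frame(i = 1L, j = 2L, order = 1L)
  expect_error(
    ligand_model(atoms, matrix(0, 2, 3), bonds, net_charge = 1L),
    "net charge")
  expect_error(
    ligand_model(atoms, matrix(0, 2, 3), bonds,
                 aromatic_rings = list(1:2)),
    "fewer than 5")
  expect_error(
    ligand_model(atoms, matrix(0, 2, 3), bonds,
                 donors = matrix(c(2L, 1L), ncol = 2)),
    "N/O/S")
})

test_that("docked-ensemble output has one MODEL and one score row per frame", {
  ens <- generate_peptide_ensemble(n_res = 4, n_frames = 2, seed = 9)
  lig <- generate_ligand(n_heavy = 3)
  de <- per_residue_ensemble_dock(ens, lig, mock_backend(1.0), seed = 1)
  prefix <- file.path(withr::local_tempdir(), "run")
  files <- write_docked_ensemble(de, prefix)
  lines <- readLines(files["pdb"])
  expect_equal(length(grep("^MODEL", lines)), 2)
  scores <- read.table(files["scores"], header = TRUE, sep = "\t")
  expect_equal(nrow(scores), 2)
  expect_equal(scores$raw_score, selected_scores(de))
  # ligand coordinates round-trip at PDB precision
  back <- read_ensemble(files["pdb"])
  lig_rows <- back$atoms$res_name == "LIG"
  expect_equal(back$coords[[1]][lig_rows, ],
               de$selected[[1]]$ligand_coords, tolerance = 1e-3)
  # empty docked ensemble rejected
  de_empty <- de
  de_empty$selected <- list()
  expect_error(write_docked_ensemble(de_empty, prefix), "empty")
})
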