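make_test_pdb <- function(path, truncate_line = NA) {
  lines <- c(
    "ATOM      1  CA  ALA A 169       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  CYS A 170       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA B 169       0.000   6.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  CYS B 170       3.800   6.000   0.000  1.00  0.00           C",
    "HETATM    5  C1  CLR A 900       1.900   3.000   1.000  1.00  0.00           C",
    "END")
  if (!is.na(truncate_line))
    lines[truncate_line] <- substr(lines[truncate_line], 1, 40)
  writeLines(lines, path)
  path
}

test_that("read_pdb splits chains, tags ligands and attaches BW positions", {
  p <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  cx <- read_pdb(p, bw_map = c("170" = "3.55"))
  expect_s3_class(cx, "dimer_complex")
  expect_setequal(cx$chains, c("A", "B"))
  expect_equal(nrow(protomer_atoms(cx, "A")), 2L)
  expect_equal(nrow(protomer_atoms(cx, "B")), 2L)
  lig <- cx$atoms[cx$atoms$is_ligand, ]
  expect_equal(nrow(lig), 1L)
  expect_equal(lig$ligand_tag, "CHOL_A")
  # the palmitoylation-site convention: residue 170 carries BW 3.55
  r170 <- cx$atoms[cx$atoms$resno == 170 & cx$atoms$chain == "A", ]
  expect_equal(unique(r170$bw), "3.55")
  expect_true(all(is.na(cx$atoms$bw[cx$atoms$resno == 169])))
})

test_that("malformed ATOM records are reported with their line number", {
  p <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"), truncate_line = 3)
  expect_error(read_pdb(p), "line 3")
})

test_that("PDB write/read round trip preserves order, ligands and coordinates", {
  cx <- make_dimer_fixture(n_residues_per_protomer = 4, separation = 6,
                           charge_scheme = "random", n_cholesterol = 2,
                           seed = 7)
  # perturb away from the grid so rounding actually matters
  set.seed(7)
  cx$atoms$x <- cx$atoms$x + runif(nrow(cx$atoms), -0.2, 0.2) + 0.1234567
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cx, p)
  back <- read_pdb(p)
  expect_equal(nrow(back$atoms), nrow(cx$atoms))
  expect_equal(back$atoms$elety, cx$atoms$elety)
  expect_equal(back$atoms$resno, cx$atoms$resno)
  # ligands come back as HETATM records
  expect_true(all(back$atoms$type[back$atoms$resid == "CLR"] == "HETATM"))
  # coordinates survive at PDB format precision (3 decimals)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(cx$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE)
  expect_error(write_pdb(dimer_complex(cx$atoms[0, ]), p))
})

test_that("attach_parameters populates charges and LJ terms or fails loudly", {
  p <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  cx <- read_pdb(p)
  params <- data.frame(residue_name = c("ALA", "CYS", "CLR"),
                       atom_name = c("CA", "CA", "C1"),
                       charge_e = c(1, -1, 0), lj_A = c(0, 0, 0),
                       lj_C = c(0, 0, 0))
  cx2 <- attach_parameters(cx, params)
  expect_equal(cx2$atoms$q[cx2$atoms$resid == "ALA"], c(1, 1))
  expect_equal(cx2$atoms$q[cx2$atoms$resid == "CYS"], c(-1, -1))
  # missing key, no default: error names the offending pair
  expect_error(attach_parameters(cx, params[-3, ]), "CLR C1")
  # declared default fills the gap
  cx3 <- attach_parameters(cx, params[-3, ],
                           default = list(charge_e = 0, lj_A = 0, lj_C = 0))
  expect_equal(cx3$atoms$q[cx3$atoms$resid == "CLR"], 0)
  # null parameters make every downstream energy zero
  zero <- data.frame(residue_name = "*", atom_name = "*",
                     charge_e = 0, lj_A = 0, lj_C = 0)
  cx4 <- attach_parameters(cx, zero,
                           default = list(charge_e = 0, lj_A = 0, lj_C = 0))
  e <- residue_vs_protomer_energy(protomer_atoms(cx4, "A"),
                                  protomer_atoms(cx4, "B"))
  expect_identical(unname(e[c("coulombic", "vdw")]), c(0, 0))
})

test_that("BW positions must be a bijection within a protomer", {
  atoms <- make_dimer_fixture(n_residues_per_protomer = 3)$atoms
  atoms$bw[atoms$chain == "A"] <- "1.1"   # two residues share 1.1
  expect_error(dimer_complex(atoms), "duplicate BW")
})

test_that("palmitoyl grafted onto a cysteine is tagged but stays in its residue", {
  p <- make_test_pdb(withr::local_tempfile(fileext = ".pdb"))
  cx <- read_pdb(p, palmitoyl_atoms = data.frame(chain = "A", resno = 170,
                                                 elety = "CA"))
  tagged <- cx$atoms[!is.na(cx$atoms$ligand_tag) & cx$atoms$ligand_tag == "PALM_A", ]
  expect_equal(nrow(tagged), 1L)
  expect_false(tagged$is_ligand)
  # excluded from the protomer pool by default, present on request
  expect_equal(nrow(protomer_atoms(cx, "A")), 1L)
  expect_equal(nrow(protomer_atoms(cx, "A", include_palmitoyl = TRUE)), 2L)
})
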