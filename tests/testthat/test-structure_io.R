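test_that("a minimal hand-written PDB parses into the expected unit", {
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1, 0, 0),
    pdb_atom_line(3, "N", "ALA", "A", 2, 3, 1, 0),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 4, 1, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 2, 5, 1.5, 0.5)))
  u <- read_structure(path)
  expect_s3_class(u, "structure_unit")
  expect_equal(n_residues(u), 2)
  expect_equal(unique(u$residues$chain), "A")
  expect_equal(u$residues$aa, c("GLY", "ALA"))
  expect_equal(nrow(u$ss_bonds), 0)
  # GLY falls back to CA; ALA effective atom is its only side-chain atom CB
  expect_equal(unlist(u$residues[1, c("x", "y", "z")]), c(x = 1, y = 0, z = 0))
  expect_equal(unlist(u$residues[2, c("x", "y", "z")]),
               c(x = 5, y = 1.5, z = 0.5))
})

test_that("only the first coordinate model is retained", {
  path <- write_mini_pdb(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 9, 9, 9),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 5, 9, 9),
    "ENDMDL"))
  u <- read_structure(path)
  expect_equal(n_residues(u), 2)
  expect_equal(u$residues$x, c(0, 4))
  expect_match(paste(u$skipped, collapse = " "), "model")
})

test_that("parse failures and empty units raise informative errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", bad)
  expect_error(read_structure(bad))
  hetonly <- write_mini_pdb(
    sub("^ATOM  ", "HETATM", pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0)))
  expect_error(read_structure(hetonly), "no protein residues")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("waters, ligands and nucleic chains are excluded and logged", {
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_atom_line(3, "O", "HOH", "A", 100, 8, 8, 8)),
    pdb_atom_line(4, "P", "DA", "B", 1, 10, 0, 0),
    sub("^ATOM  ", "HETATM", pdb_atom_line(5, "C1", "NAG", "C", 1, 12, 0, 0))))
  u <- read_structure(path)
  expect_equal(n_residues(u), 2)
  expect_match(paste(u$skipped, collapse = "; "), "water")
  expect_match(paste(u$skipped, collapse = "; "), "nucleic")
  expect_match(paste(u$skipped, collapse = "; "), "NAG")
})

test_that("alternate locations keep the highest occupancy, ties the first", {
  path <- write_mini_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1, 0, 0, alt = "A", occ = 0.4),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 2, 0, 0, alt = "B", occ = 0.6),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 6, 0, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 2, 7, 0, 0, alt = "A", occ = 0.5),
    pdb_atom_line(6, "CB", "ALA", "A", 2, 8, 0, 0, alt = "B", occ = 0.5)))
  u <- read_structure(path)
  expect_equal(u$residues$x, c(2, 7)) # occ 0.6 wins; tie keeps first seen
})

test_that("effective atom follows the side-chain centroid rule", {
  # GLY with CA at origin -> origin (fallback)
  g <- write_mini_pdb(c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                        pdb_atom_line(2, "CA", "GLY", "A", 2, 5, 0, 0)))
  u <- read_structure(g)
  expect_equal(unlist(u$residues[1, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0))
  # VAL side-chain mean checked by hand: CB, CG1, CG2
  v <- write_mini_pdb(c(
    pdb_atom_line(1, "N", "VAL", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "VAL", "A", 1, 0.5, 0, 0),
    pdb_atom_line(3, "C", "VAL", "A", 1, 0, 0.5, 0),
    pdb_atom_line(4, "O", "VAL", "A", 1, 0, 0, 0.5),
    pdb_atom_line(5, "CB", "VAL", "A", 1, 1, 2, 3),
    pdb_atom_line(6, "CG1", "VAL", "A", 1, 2, 3, 4),
    pdb_atom_line(7, "CG2", "VAL", "A", 1, 3, 4, 8),
    pdb_atom_line(8, "CA", "GLY", "A", 2, 9, 9, 9)))
  u <- read_structure(v)
  expect_equal(unlist(u$residues[1, c("x", "y", "z")]),
               c(x = mean(c(1, 2, 3)), y = mean(c(2, 3, 4)),
                 z = mean(c(3, 4, 8))))
  # non-glycine residue with backbone only -> CA with a warning
  m <- write_mini_pdb(c(pdb_atom_line(1, "CA", "MET", "A", 1, 1, 1, 1),
                        pdb_atom_line(2, "CA", "GLY", "A", 2, 5, 5, 5)))
  expect_warning(u <- read_structure(m), "CA used")
  expect_equal(u$residues$effective[1], "ca")
})

test_that("effective atoms are equivariant under rigid transforms", {
  lines <- c(
    pdb_atom_line(1, "CB", "VAL", "A", 1, 1, 2, 3),
    pdb_atom_line(2, "CG1", "VAL", "A", 1, 2, 3, 4),
    pdb_atom_line(3, "CG2", "VAL", "A", 1, 3, 4, 8),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 9, 9, 9))
  u <- read_structure(write_mini_pdb(lines))
  rot <- random_rotation(7)
  shift <- c(3, -2, 5)
  u2 <- effective_atoms(rigid_transform(u, rot, shift))
  expected <- sweep(as.matrix(u$residues[, c("x", "y", "z")]) %*% t(rot),
                    2, shift, "+")
  expect_equal(as.matrix(u2$residues[, c("x", "y", "z")]), expected,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("hydrophobicity assignment follows the scale contract", {
  u <- make_unit(matrix(rnorm(30), 10), aa = c("ILE", "ARG"))
  # constant scale: every residue gets 1.0
  const <- setNames(rep(1, 20), names(hydro_scale()))
  expect_equal(assign_hydrophobicity(u, const)$residues$H, rep(1, 10))
  # min-max rescale: most hydrophobic 1, least 0
  sc <- hydro_scale("kd")
  expect_equal(unname(sc["ILE"]), 1)
  expect_equal(unname(sc["ARG"]), 0)
  raw <- setNames(seq(-2, 7, length.out = 20), names(sc))
  expect_equal(unname(hydro_scale(raw)), (raw - (-2)) / 9,
               ignore_attr = TRUE)
  u <- assign_hydrophobicity(u, "kd")
  expect_equal(u$residues$H, rep(unname(sc[c("ILE", "ARG")]), 5))
  # idempotent and order-independent
  expect_identical(assign_hydrophobicity(u, "kd")$residues$H, u$residues$H)
  perm <- sample(10)
  up <- make_unit(matrix(rnorm(30), 10)[perm, ],
                  aa = c("ILE", "ARG")[rep(1:2, 5)][perm])
  expect_equal(assign_hydrophobicity(up, "kd")$residues$H,
               u$residues$H[perm])
})

test_that("MSE maps to MET leniently and errors under strict policy", {
  lines <- c(
    sub("^ATOM  ", "HETATM", pdb_atom_line(1, "CA", "MSE", "A", 1, 0, 0, 0)),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 5, 0, 0))
  expect_warning(u <- read_structure(write_mini_pdb(lines)), "CA used")
  expect_equal(u$residues$aa[1], "MET")
  expect_equal(assign_hydrophobicity(u)$residues$H[1],
               unname(hydro_scale()["MET"]))
  expect_error(read_structure(write_mini_pdb(lines), nonstandard = "strict"),
               "MSE")
})

test_that("PDB round trip preserves the unit to field precision", {
  u <- synthesize_unit(n = 60, seed = 3, sigmas = c(8, 7, 6),
                       mode = "ideal_micelle", n_ss_bonds = 2)
  path <- tempfile(fileext = ".pdb")
  write_structure(u, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "SSBOND")), 2)
  u2 <- suppressWarnings(assign_hydrophobicity(read_structure(path)))
  expect_equal(n_residues(u2), n_residues(u))
  expect_equal(u2$residues$chain, u$residues$chain)
  expect_equal(u2$residues$resno, u$residues$resno)
  expect_equal(u2$residues$aa, u$residues$aa)
  expect_equal(u2$ss_bonds$resno1, u$ss_bonds$resno1)
  expect_equal(u2$ss_bonds$resno2, u$ss_bonds$resno2)
  expect_equal(as.matrix(u2$residues[, c("x", "y", "z")]),
               as.matrix(u$residues[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(u2$residues$H, u$residues$H)
  # mmCIF is declined, out-of-range coordinates refused
  expect_error(read_structure(path, format = "mmcif"), "mmCIF")
  u$atoms$x[1] <- 12345
  u$residues$x[1] <- 12345
  expect_error(write_structure(u, tempfile()), "field width")
})

test_that("duplicate residue identities and bad SS bonds are rejected", {
  res <- data.frame(chain = "A", resno = c(1, 1), icode = "",
                    aa = c("GLY", "ALA"), x = 0:1, y = 0, z = 0,
                    H = NA_real_, effective = "ca")
  atoms <- data.frame(res_idx = 1:2, elety = "CA", x = 0:1, y = 0, z = 0)
  expect_error(structure_unit(res, atoms), "duplicate")
  u <- make_unit(matrix(rnorm(9), 3), aa = c("CYS", "ALA", "CYS"))
  bad <- data.frame(chain1 = "A", resno1 = 1, icode1 = "",
                    chain2 = "A", resno2 = 2, icode2 = "")
  expect_error(structure_unit(u$residues, u$atoms, bad), "not a cysteine")
})
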