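# Structure parsing, eligibility, environment extraction, missing-residue
# detection and PDB round-trips.

write_lines <- function(lines, path) writeLines(lines, path)

pdb_fixture <- function(lines, resolution = TRUE) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  hdr <- c("EXPDTA    X-RAY DIFFRACTION")
  if (resolution) hdr <- c(hdr, "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.")
  writeLines(c(hdr, lines, "END"), path)
  path
}

atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                      element, record = "ATOM", occ = 1, b = 10,
                      alt = " ") {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resname, chain, resno, x, y, z,
          occ, b, element)
}

test_that("a minimal handcrafted PDB parses to one residue with five atoms", {
  path <- pdb_fixture(c(
    atom_line(1, "N", "ALA", "A", 1, -1.2, 0, 0, "N"),
    atom_line(2, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_line(3, "C", "ALA", "A", 1, 1.3, 0, 0, "C"),
    atom_line(4, "O", "ALA", "A", 1, 1.8, 1.1, 0, "O"),
    atom_line(5, "CB", "ALA", "A", 1, 0, 1.5, 0, "C")
  ))
  s <- read_pdb(path)
  expect_s3_class(s, "vxm_structure")
  expect_equal(nrow(s$atoms), 5)
  expect_equal(nrow(residue_table(s)), 1)
  expect_equal(s$atoms$element, c("N", "C", "C", "O", "C"))
  expect_equal(s$method, "X-RAY DIFFRACTION")
  expect_equal(s$resolution, 1.8)
})

test_that("waters and hydrogens are dropped; water-only files error", {
  path <- pdb_fixture(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    atom_line(2, "HB1", "ALA", "A", 1, 0.5, 0.5, 0, "H"),
    atom_line(3, "O", "HOH", "A", 101, 5, 5, 5, "O", record = "HETATM"),
    atom_line(4, "O", "HOH", "A", 102, 6, 6, 6, "O", record = "HETATM"),
    atom_line(5, "O", "HOH", "A", 103, 7, 7, 7, "O", record = "HETATM")
  ))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 1)
  expect_false(any(s$atoms$resname == "HOH"))

  only_water <- pdb_fixture(c(
    atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, "O", record = "HETATM")
  ))
  expect_error(read_pdb(only_water), "empty structure")
})

test_that("altloc keeps the highest-occupancy conformer", {
  path <- pdb_fixture(c(
    atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C", alt = "A", occ = 0.4),
    atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, "C", alt = "B", occ = 0.6),
    atom_line(3, "CB", "ALA", "A", 1, 1, 1, 1, "C")
  ))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(ca$x, 9)
})

test_that("eligibility accepts only sub-3A X-ray structures", {
  s <- toy_structure()
  expect_true(check_eligibility(s)$accept)

  nmr <- toy_structure(method = "SOLUTION NMR", resolution = NA_real_)
  nmr$resolution <- 2.0  # even with a nominal resolution, method rejects
  r <- check_eligibility(nmr)
  expect_false(r$accept)
  expect_equal(r$reason, "method")

  low <- toy_structure(resolution = 3.2)
  r <- check_eligibility(low)
  expect_false(r$accept)
  expect_equal(r$reason, "resolution")

  exact <- toy_structure(resolution = 3.0)  # boundary: strict <
  expect_false(check_eligibility(exact)$accept)

  missing <- toy_structure(method = NA_character_)
  expect_equal(check_eligibility(missing)$reason, "missing_metadata")
})

make_env_structure <- function(extra = NULL) {
  atoms <- one_residue_atoms()
  if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
  toy_structure(atoms)
}

test_that("environment membership matches a brute-force distance scan", {
  # second residue with atoms at controlled distances from the CA at origin
  extra <- dplyr::bind_rows(
    atom_row(6, "CA", "C", "GLY", "A", 2, 9.0, 0, 0),
    atom_row(7, "N",  "N", "GLY", "A", 2, 10.1, 0, 0),
    atom_row(8, "C",  "C", "GLY", "A", 2, 12.0, 0, 0)
  )
  s <- make_env_structure(extra)
  v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p1")
  e <- extract_environment(s, v, radius = 10)

  at <- s$atoms
  d <- sqrt(at$x^2 + at$y^2 + at$z^2)  # CA of residue 1 is at the origin
  expect_setequal(e$atoms$serial, at$serial[d <= 10])
  # the 10.1 A atom is excluded, the 9.0 A one included
  expect_false(7 %in% e$atoms$serial)
  expect_true(6 %in% e$atoms$serial)
  # residue 2 contributes >= 1 atom so it is in the residue set, but only
  # its in-radius atoms are in the atom set
  expect_true(2 %in% e$residues$resno)
  expect_false(any(e$atoms$serial == 8))
  # variant residue is always a member
  expect_true(1 %in% e$residues$resno)
})

test_that("environment extraction validates residue, CA and wildtype", {
  s <- make_env_structure()
  expect_error(
    extract_environment(s, variant_record("toy", "A", 99, "A", "V",
                                          protein_id = "p")),
    "not found")
  expect_error(
    extract_environment(s, variant_record("toy", "A", 1, "G", "V",
                                          protein_id = "p")),
    "mismatch")
  no_ca <- toy_structure(one_residue_atoms()[-2, ])
  expect_error(
    extract_environment(no_ca, variant_record("toy", "A", 1, "A", "V",
                                              protein_id = "p")),
    "C-alpha")
})

test_that("missing-residue detection reports only environment-flanking gaps", {
  # residues 1, 2, 4 on one chain: gap at 3
  atoms <- dplyr::bind_rows(
    one_residue_atoms(resno = 1),
    one_residue_atoms(resno = 2, offset = c(3.8, 0, 0)),
    one_residue_atoms(resno = 4, offset = c(7.6, 0, 0))
  )
  s <- toy_structure(atoms)
  v <- variant_record("toy", "A", 1, "A", "V", protein_id = "p")
  e <- extract_environment(s, v, radius = 15)
  gaps <- detect_missing_residues(s, e)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$before_resno, 2)
  expect_equal(gaps$after_resno, 4)
  expect_equal(gaps$n_missing, 1L)

  # continuous numbering: no gaps
  cont <- toy_structure(dplyr::bind_rows(
    one_residue_atoms(resno = 1),
    one_residue_atoms(resno = 2, offset = c(3.8, 0, 0))
  ))
  e2 <- extract_environment(cont, v, radius = 15)
  expect_equal(nrow(detect_missing_residues(cont, e2)), 0)

  # gap far outside the environment: flanks beyond the radius
  far <- toy_structure(dplyr::bind_rows(
    one_residue_atoms(resno = 1),
    one_residue_atoms(resno = 30, offset = c(40, 0, 0)),
    one_residue_atoms(resno = 32, offset = c(44, 0, 0))
  ))
  e3 <- extract_environment(far, v, radius = 10)
  expect_equal(nrow(detect_missing_residues(far, e3)), 0)
})

test_that("write/read round-trips preserve atoms to PDB precision", {
  s <- synth_structure(20, seed = 3, helix_length = 20, id = "rt")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path, id = "rt")
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$x, round(s$atoms$x, 3))
  expect_equal(s2$atoms$y, round(s$atoms$y, 3))
  expect_equal(s2$atoms$z, round(s$atoms$z, 3))
  expect_equal(s2$method, s$method)
  expect_equal(s2$resolution, s$resolution)

  # parsing is idempotent: read(write(read)) == read
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, path2)
  s3 <- read_pdb(path2, id = "rt")
  expect_equal(s3$atoms, s2$atoms)

  # format precision: 1.23456 is stored as 1.235
  a <- one_residue_atoms()
  a$x[1] <- 1.23456
  sp <- toy_structure(a)
  p3 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sp, p3)
  expect_equal(read_pdb(p3)$atoms$x[1], 1.235)
})

test_that("variant tables round-trip through TSV", {
  v <- tibble::tibble(
    structure_id = c("s1", "s1"), chain = c("A", "B"),
    resnum = c(10L, 20L), wt = c("A", "G"), var = c("V", "R"),
    label = c("benign", "pathogenic"), protein_id = c("p1", "p1"),
    inheritance = c("AD", NA)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(v, path)
  v2 <- read_variants(path)
  expect_equal(as.data.frame(v2), as.data.frame(v))
})
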