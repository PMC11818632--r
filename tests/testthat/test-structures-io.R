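test_that("PDB round-trip preserves chains, residues and coordinates", {
  ir <- syntheticIRDefinition(c(3, 10), c(6, 13))
  cx <- makeToyComplex(seed = 5, receptorLength = 20, ir = ir,
                       plantedIrHits = 3, plantedExtraContacts = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(cx, f)
  m2 <- readStructure(f, source = "SYNTHETIC")
  expect_equal(chainIds(m2), chainIds(cx))
  a1 <- atoms(cx); a2 <- atoms(m2)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
  expect_equal(a2$z, a1$z, tolerance = 1e-3)
  # both chains are TER-terminated on disk
  expect_equal(sum(grepl("^TER", readLines(f))), 2L)
})

test_that("a 361-residue receptor model parses with the full residue count", {
  cx <- makeToyComplex(seed = 1, receptorLength = 361,
                       plantedIrHits = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(cx, f)
  m <- readStructure(f, source = "SYNTHETIC")
  expect_length(residueNumbers(m, "A"), 361L)
})

test_that("waters and hydrogens are dropped; water-only files error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1L, 1L, 0, 0, 0),
    sprintf("ATOM  %5d  H   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           H",
            2L, 1L, 1, 0, 0),
    sprintf("ATOM  %5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            3L, 2L, 5, 0, 0),
    "END")
  writeLines(lines, f)
  m <- readStructure(f)
  expect_equal(nrow(atoms(m)), 1L)
  expect_equal(atoms(m)$element, "C")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[3:4], f2)
  expect_error(readStructure(f2), "empty model")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
    "END"), f)
  m <- readStructure(f)
  expect_equal(nrow(atoms(m)), 1L)
  expect_equal(atoms(m)$x, 9.0)
})

test_that("element radii follow the fixed heavy-atom table", {
  cx <- makeToyComplex(seed = 1, receptorLength = 25,
                       ir = syntheticIRDefinition(1, 5), plantedIrHits = 0)
  a <- atoms(cx)
  expect_equal(unique(a$radius[a$element == "C"]), 1.70)
  expect_equal(unique(a$radius[a$element == "N"]), 1.55)
  expect_equal(unique(a$radius[a$element == "O"]), 1.52)
})

test_that("renumbering shifts one chain and rejects out-of-model chains", {
  ir <- syntheticIRDefinition(1, 3)
  cx <- makeToyComplex(seed = 2, receptorLength = 5, ir = ir,
                       plantedIrHits = 1)
  expect_equal(residueNumbers(renumberToReference(cx, "A", 0), "A"), 1:5)
  m <- renumberToReference(cx, "A", 10)
  expect_equal(residueNumbers(m, "A"), 11:15)
  expect_equal(residueNumbers(m, "B"), residueNumbers(cx, "B"))
  expect_error(renumberToReference(cx, "Z", 1), "no chain")
})

test_that("chain-block order in the file does not change the parsed model", {
  ir <- syntheticIRDefinition(2, 4)
  cx <- makeToyComplex(seed = 3, receptorLength = 10, ir = ir,
                       plantedIrHits = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(cx, f)
  lines <- readLines(f)
  is_b <- grepl("^ATOM.{17}B", lines)
  is_a <- grepl("^ATOM.{17}A", lines)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[is_b], "TER", lines[is_a], "TER", "END"), f2)
  m1 <- readStructure(f)
  m2 <- readStructure(f2)
  for (ch in c("A", "B")) {
    a1 <- atoms(m1)[atoms(m1)$chain == ch, ]
    a2 <- atoms(m2)[atoms(m2)$chain == ch, ]
    expect_equal(a2$resno, a1$resno)
    expect_equal(a2$x, a1$x)
  }
})
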