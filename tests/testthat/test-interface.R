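test_that("chains far apart yield an empty interface in both modes", {
  ir <- syntheticIRDefinition(2, 6)
  cx <- makeToyComplex(seed = 1, receptorLength = 12, ir = ir,
                       plantedIrHits = 0, plantedExtraContacts = 0)
  for (mode in c("dsasa", "distance")) {
    r <- findInterfaceResidues(cx, "A", "B", mode)
    expect_equal(receptorTotalCount(r), 0L)
    expect_equal(nrow(ligandInterfacing(r)), 0L)
  }
})

test_that("buried-area and distance definitions agree on planted interfaces", {
  ir <- syntheticIRDefinition(c(5, 20, 40), c(12, 28, 47))
  for (seed in 1:5) {
    cx <- makeToyComplex(seed = seed, receptorLength = 60, ir = ir,
                         plantedIrHits = 6, plantedExtraContacts = 3)
    ds <- findInterfaceResidues(cx, "A", "B", "dsasa")
    di <- findInterfaceResidues(cx, "A", "B", "distance")
    expect_identical(receptorInterfacing(ds)$resno,
                     receptorInterfacing(di)$resno)
    # and both equal the brute-force contact oracle
    expect_identical(receptorInterfacing(di)$resno,
                     oracle_contact_residues(cx, "A", "B", 5.0))
  }
})

test_that("a fixture burying 44 IR residues reports 44 hits of 59 total", {
  cx <- makeToyComplex(seed = 1, plantedIrHits = 44,
                       plantedExtraContacts = 15)
  r <- findInterfaceResidues(cx, "A", "B", "dsasa")
  cov <- irCoverage(r, syntheticAtaxin3IR())
  expect_equal(cov$irHits, 44L)
  expect_equal(cov$totalInterfacing, 59L)
  expect_equal(receptorTotalCount(r), 59L)
})

test_that("swapping receptor and ligand labels swaps the two sets", {
  ir <- syntheticIRDefinition(c(3, 10), c(6, 15))
  cx <- makeToyComplex(seed = 7, receptorLength = 20, ir = ir,
                       plantedIrHits = 3, plantedExtraContacts = 1)
  ab <- findInterfaceResidues(cx, "A", "B", "dsasa")
  ba <- findInterfaceResidues(cx, "B", "A", "dsasa")
  expect_equal(receptorInterfacing(ba), ligandInterfacing(ab))
  expect_equal(ligandInterfacing(ba), receptorInterfacing(ab))
})

test_that("raising bsaMin or lowering contactCutoff never adds residues", {
  ir <- syntheticIRDefinition(c(3, 10), c(6, 15))
  cx <- makeToyComplex(seed = 9, receptorLength = 20, ir = ir,
                       plantedIrHits = 4, plantedExtraContacts = 1)
  loose <- findInterfaceResidues(cx, "A", "B", "dsasa", bsaMin = 0.1)
  tight <- findInterfaceResidues(cx, "A", "B", "dsasa", bsaMin = 5)
  expect_true(all(receptorInterfacing(tight)$resno %in%
                  receptorInterfacing(loose)$resno))
  far <- findInterfaceResidues(cx, "A", "B", "distance", contactCutoff = 6)
  near <- findInterfaceResidues(cx, "A", "B", "distance", contactCutoff = 3)
  expect_true(all(receptorInterfacing(near)$resno %in%
                  receptorInterfacing(far)$resno))
})

test_that("degenerate chain selections are rejected", {
  ir <- syntheticIRDefinition(1, 3)
  cx <- makeToyComplex(seed = 1, receptorLength = 5, ir = ir,
                       plantedIrHits = 1)
  expect_error(findInterfaceResidues(cx, "A", "A"), "must differ")
  expect_error(findInterfaceResidues(cx, "A", "C"), "not in model")
  solo <- StructureModel(atoms(cx)[atoms(cx)$chain == "A", ],
                         source = "SYNTHETIC")
  expect_error(findInterfaceResidues(solo, "A", "B"), "two chains")
})
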