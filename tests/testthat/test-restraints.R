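perfect_preds <- function(truth, len, n = 4) {
  lapply(seq_len(n), function(i)
    list(name = paste0("p", i), resno = seq_len(len),
         flag = seq_len(len) %in% truth, score = NULL))
}

test_that("vote thresholds behave as a CPORT-style consensus", {
  preds <- perfect_preds(c(3, 7), 10)
  preds[[1]]$flag[5] <- TRUE  # one predictor flags residue 5
  expect_true(3 %in% consensusActive(preds, minVotes = 2))
  expect_false(5 %in% consensusActive(preds, minVotes = 2))
  expect_true(5 %in% consensusActive(preds, minVotes = 1))
})

test_that("noisy synthetic predictors match exhaustive vote counting", {
  truth <- 30:49  # planted 20-residue patch
  preds <- makePredictorOutputs(truth, proteinLength = 100,
                                sensitivity = 0.8, specificity = 0.9,
                                nPredictors = 4, seed = 7)
  for (mv in 1:4)
    expect_identical(consensusActive(preds, minVotes = mv),
                     oracle_votes(preds, mv))
})

test_that("raising minVotes never adds active residues", {
  preds <- makePredictorOutputs(10:20, proteinLength = 60,
                                sensitivity = 0.7, specificity = 0.85,
                                nPredictors = 4, seed = 11)
  prev <- consensusActive(preds, minVotes = 1)
  for (mv in 2:4) {
    cur <- consensusActive(preds, minVotes = mv)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("length disagreement and invalid vote counts are rejected", {
  preds <- perfect_preds(2, 10, n = 2)
  preds[[2]]$resno <- 1:9
  preds[[2]]$flag <- preds[[2]]$flag[1:9]
  expect_error(consensusActive(preds, 1), "disagree")
  expect_error(consensusActive(perfect_preds(1, 5), 9), "minVotes")
  expect_error(consensusActive(list(), 1), "at least one")
})

test_that("passive set matches a brute-force distance oracle", {
  ir <- syntheticIRDefinition(1, 5)
  cx <- makeToyComplex(seed = 2, receptorLength = 16, ir = ir,
                       plantedIrHits = 0)
  model <- StructureModel(atoms(cx)[atoms(cx)$chain == "A", ],
                          source = "SYNTHETIC")
  active <- c(5L, 6L, 10L)
  rs <- passiveFromActive(model, active, chain = "A",
                          neighborRadius = 11, rsaMin = 0.15)
  expect_identical(sort(passiveResidues(rs)),
                   oracle_passive(model, active, "A", 11, 0.15))
  expect_identical(activeResidues(rs), active)
  expect_length(intersect(activeResidues(rs), passiveResidues(rs)), 0L)
})

test_that("degenerate passive inputs give empty passive sets", {
  ir <- syntheticIRDefinition(1, 3)
  cx <- makeToyComplex(seed = 1, receptorLength = 8, ir = ir,
                       plantedIrHits = 0)
  model <- StructureModel(atoms(cx)[atoms(cx)$chain == "A", ],
                          source = "SYNTHETIC")
  expect_length(passiveResidues(
    passiveFromActive(model, integer(), chain = "A")), 0L)
  expect_length(passiveResidues(
    passiveFromActive(model, 3L, chain = "A", neighborRadius = 0)), 0L)
  expect_error(passiveFromActive(model, 99L, chain = "A"), "not in model")
})

test_that("restraint tables round-trip through their file format", {
  rs <- new("RestraintSet", active = c(4L, 2L), passive = c(9L, 7L, 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRestraints(rs, f)
  expect_equal(length(readLines(f)), 6L)  # header + 5 rows
  back <- readRestraints(f)
  expect_equal(sort(activeResidues(back)), c(2L, 4L))
  expect_equal(sort(passiveResidues(back)), c(5L, 7L, 9L))

  empty <- new("RestraintSet", active = integer(), passive = integer())
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeRestraints(empty, f2)
  expect_equal(length(readLines(f2)), 1L)  # header only
  expect_length(activeResidues(readRestraints(f2)), 0L)
})
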