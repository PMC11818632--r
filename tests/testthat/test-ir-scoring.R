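test_that("IR coverage arithmetic reproduces the published convention", {
  ir <- syntheticAtaxin3IR()
  expect_equal(irTotalResidues(ir), 61L)
  res <- irResidues(ir)
  expect_equal(irCoverage(res[1:44], ir)$irCoveragePct, 72.131)
  expect_equal(irCoverage(integer(), ir)$irCoveragePct, 0)
  expect_equal(irCoverage(res, ir)$irCoveragePct, 100)
  expect_equal(irCoverage(res[1:47], ir)$irCoveragePct, 77.049)
})

test_that("non-IR residues change only the total interfacing count", {
  ir <- syntheticAtaxin3IR()
  base <- irResidues(ir)[1:20]
  extra <- setdiff(1:361, irResidues(ir))[1:30]
  c1 <- irCoverage(base, ir)
  c2 <- irCoverage(c(base, extra), ir)
  expect_equal(c2$irHits, c1$irHits)
  expect_equal(c2$irCoveragePct, c1$irCoveragePct)
  expect_equal(c2$totalInterfacing, c1$totalInterfacing + 30L)
})

test_that("IR residues outside the receptor range are rejected", {
  ir <- syntheticIRDefinition(c(1, 350), c(5, 370))
  expect_error(irCoverage(1:3, ir, receptorLength = 361), "outside")
  expect_error(irCoverage(400L, syntheticAtaxin3IR(),
                          receptorLength = 361), "outside")
})

test_that("two-stage classification prefers AlphaFold and is strict at 50", {
  rec <- function(cov, found = TRUE)
    list(solutionFound = found, irCoveragePct = cov)
  expect_equal(classifyInteractor(rec(72.131), NULL), "TRUE_INTERACTOR_AF")
  expect_equal(classifyInteractor(rec(NA, found = FALSE), rec(52.459)),
               "TRUE_INTERACTOR_DIT")
  expect_equal(classifyInteractor(rec(45.902), rec(45.902)),
               "NOT_SUPPORTED")
  expect_equal(classifyInteractor(rec(NA, FALSE), rec(NA, FALSE)),
               "NO_SOLUTION")
  # strictly greater than 50: 50.820 passes, exactly 50.000 fails
  expect_equal(classifyInteractor(rec(50.820), NULL), "TRUE_INTERACTOR_AF")
  expect_equal(classifyInteractor(rec(50.000), NULL), "NOT_SUPPORTED")
  # an AlphaFold pass is never deferred to D-I-TASSER
  expect_equal(classifyInteractor(rec(60), rec(90)), "TRUE_INTERACTOR_AF")
  expect_error(classifyInteractor(NULL, NULL), "at least one")
})

test_that("classification is monotone in coverage", {
  rec <- function(cov) list(solutionFound = TRUE, irCoveragePct = cov)
  rank <- c(NOT_SUPPORTED = 0, TRUE_INTERACTOR_AF = 1)
  covs <- seq(0, 100, by = 5)
  got <- rank[vapply(covs, function(cc)
    classifyInteractor(rec(cc), NULL), character(1))]
  expect_true(all(diff(got) >= 0))
})

test_that("cohort summaries count statuses and reject duplicate proteins", {
  af <- data.frame(uniprot = c("P00001", "P00002"), gene = c("g1", "g2"),
                   solution_found = TRUE, ir_coverage_pct = c(70, 30))
  dit <- data.frame(uniprot = "P00002", gene = "g2",
                    solution_found = TRUE, ir_coverage_pct = 55)
  cl <- classifyCohort(af, dit)
  tab <- tabulateCohort(cl)
  expect_equal(unname(tab$counts["TRUE_INTERACTOR_AF"]), 1L)
  expect_equal(unname(tab$counts["TRUE_INTERACTOR_DIT"]), 1L)
  expect_equal(tab$nTrue, 2L)
  # table sorted by descending supporting coverage
  expect_equal(tab$table$uniprot, c("P00001", "P00002"))

  expect_error(tabulateCohort(rbind(cl, cl)), "duplicate")
  empty <- tabulateCohort(cl[0, ])
  expect_equal(sum(empty$counts), 0L)
  expect_equal(empty$nTrue, 0L)
})
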