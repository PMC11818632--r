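plist <- function(...) {
  rows <- list(...)
  data.frame(gene = vapply(rows, `[[`, "", 1),
             uniprot = vapply(rows, `[[`, "", 2),
             gene_id = as.integer(vapply(rows, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

test_that("list operations follow set semantics with stable order", {
  a <- plist(c("ATXN3", "P54252", "4287"), c("Parkin", "O60260", "5071"),
             c("VCP", "P55072", "7415"))
  b <- plist(c("Parkin", "O60260", "5071"))
  expect_equal(intersectProteins(a, a), a)
  expect_equal(nrow(excludeProteins(a, a)), 0L)
  got <- intersectProteins(a, b)
  expect_equal(got$uniprot, "O60260")
  expect_equal(excludeProteins(a, b)$uniprot, c("P54252", "P55072"))
  # order of the first list is preserved
  expect_equal(intersectProteins(a, a[3:1, ])$uniprot, a$uniprot)
})

test_that("duplicate identifiers collapse with a warning", {
  a <- plist(c("VCP", "P55072", "7415"), c("VCP", "P55072", "7415"))
  b <- plist(c("VCP", "P55072", "7415"))
  expect_warning(got <- intersectProteins(a, b), "duplicate")
  expect_equal(nrow(got), 1L)
})

test_that("identifier files validate accessions and report bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("VCP\tP55072\t7415", "Parkin\tO60260\t5071"), f)
  d <- readProteinList(f)
  expect_equal(d$uniprot, c("P55072", "O60260"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("VCP\tP55072\t7415", "broken-line"), f2)
  expect_error(readProteinList(f2), "line 2")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("VCP\tNOTANID\t7415", f3)
  expect_error(readProteinList(f3), "UniProt")
})

sca3_tissues <- c("cerebral cortex", "basal ganglia", "thalamus",
                  "midbrain", "pons", "medulla oblongata", "cerebellum")

make_expr <- function() {
  # VCP detected everywhere, Parkin only in cerebellum, ATXN3 nowhere
  rows <- expand.grid(gene = c("P55072", "O60260", "P54252"),
                      tissue = sca3_tissues, stringsAsFactors = FALSE)
  rows$level <- ifelse(rows$gene == "P55072", 12.5,
                ifelse(rows$gene == "O60260" &
                         rows$tissue == "cerebellum", 3.1, 0))
  rows
}

test_that("expression filtering keeps proteins by tissue detection", {
  prots <- plist(c("VCP", "P55072", "7415"), c("Parkin", "O60260", "5071"),
                 c("ATXN3", "P54252", "4287"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(make_expr(), f, sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- readExpressionTable(f)

  all7 <- expressionFilter(prots, expr, sca3_tissues, requireAll = TRUE)
  expect_equal(all7$uniprot, "P55072")
  any1 <- expressionFilter(prots, expr, sca3_tissues, requireAll = FALSE)
  expect_setequal(any1$uniprot, c("P55072", "O60260"))
  # require_all output is a subset of the require_any output
  expect_true(all(all7$uniprot %in% any1$uniprot))
  expect_true(all(any1$uniprot %in% prots$uniprot))

  expect_error(expressionFilter(prots, expr, "hippocampus"),
               "absent from table")
  expect_error(expressionFilter(prots, expr, character()), "nonempty")
})

test_that("duplicate (gene, tissue) expression rows are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttissue\tlevel", "P55072\tpons\t1",
               "P55072\tpons\t2"), f)
  expect_error(readExpressionTable(f), "duplicate")
})
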