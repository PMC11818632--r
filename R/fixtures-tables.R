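#' Packaged ataxin-3 mitophagy docking cohort
#'
#' Loads the packaged transcription of the published ataxin-3 mitophagy
#' docking cohort: per-protein IR coverage results of the 68 candidate
#' interactors docked against the wild-type ataxin-3 receptor using
#' AlphaFold and, where the AlphaFold run failed or did not pass,
#' D-I-TASSER ligand structures, plus the expanded-vs-WT interfacing count
#' pairs. File integrity is verified against a packaged MD5 manifest
#' before parsing.
#'
#' @return list with elements:
#' \describe{
#'   \item{afReported}{27 reported interactors with an AlphaFold docking
#'     solution (coverage \%, IR hits of 61, total interfacing of 361).}
#'   \item{ditReported}{17 reported interactors re-docked with D-I-TASSER
#'     structures; \code{af_failed} marks proteins whose AlphaFold docking
#'     produced no solution.}
#'   \item{afNovel}{31 non-reported candidates with an AlphaFold
#'     solution.}
#'   \item{ditNovel}{21 non-reported candidates re-docked with D-I-TASSER
#'     structures (\code{af_failed} as above).}
#'   \item{differential}{45 true interactors with expanded (E) and
#'     wild-type (W) interfacing counts and the published differential
#'     percentage (\code{delta_printed}, at its printed precision).}
#'   \item{noSolution}{proteins with no docking solution (or no structure)
#'     for a given source, completing the 68-protein cohort.}
#' }
#' @examples
#' tabs <- ataxin3DockingTables()
#' nrow(tabs$afReported)  # 27
#' @export
ataxin3DockingTables <- function() {
  ext <- system.file("extdata", package = "p2dock", mustWork = TRUE)
  manifest <- read.table(file.path(ext, "MANIFEST.md5"),
                         col.names = c("md5", "file"),
                         stringsAsFactors = FALSE)
  files <- grep("^ataxin3_", manifest$file, value = TRUE)
  actual <- tools::md5sum(file.path(ext, files))
  expected <- manifest$md5[match(files, manifest$file)]
  bad <- files[unname(actual) != expected]
  if (length(bad))
    stop("packaged fixture checksum mismatch: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rd <- function(f) {
    # delta_printed keeps its printed text form so trailing zeros (and
    # hence the printed precision) survive; a numeric copy sits alongside
    d <- read.delim(file.path(ext, f), stringsAsFactors = FALSE,
                    colClasses = if (grepl("differential", f))
                      c(delta_printed = "character") else NA)
    if ("af_failed" %in% names(d)) d$af_failed <- d$af_failed == 1
    if ("delta_printed" %in% names(d))
      d$delta_value <- as.numeric(d$delta_printed)
    d
  }
  list(afReported = rd("ataxin3_af_reported.tsv"),
       ditReported = rd("ataxin3_dit_reported.tsv"),
       afNovel = rd("ataxin3_af_novel.tsv"),
       ditNovel = rd("ataxin3_dit_novel.tsv"),
       differential = rd("ataxin3_differential.tsv"),
       noSolution = rd("ataxin3_no_solution.tsv"))
}

#' Assemble per-source docking record tables for the full 68-protein cohort
#'
#' Turns the packaged cohort tables into the two per-source record tables
#' [classifyCohort()] consumes: one AlphaFold table and one D-I-TASSER
#' table, each with one row per protein and columns \code{uniprot},
#' \code{gene}, \code{solution_found}, \code{ir_coverage_pct}. Proteins
#' marked \code{af_failed} in the D-I-TASSER tables contribute a
#' no-solution AlphaFold record; the explicit no-solution list contributes
#' the remaining failed records (e.g. a protein with no structure in
#' either source).
#'
#' @param tabs cohort list from [ataxin3DockingTables()].
#' @return list with data.frames \code{af} and \code{dit}.
#' @export
ataxin3CohortRecords <- function(tabs = ataxin3DockingTables()) {
  solved <- function(d) data.frame(
    uniprot = d$uniprot, gene = d$gene, solution_found = TRUE,
    ir_coverage_pct = d$ir_coverage_pct, stringsAsFactors = FALSE)
  failed <- function(up, gene) data.frame(
    uniprot = up, gene = gene, solution_found = FALSE,
    ir_coverage_pct = NA_real_, stringsAsFactors = FALSE)

  af <- rbind(solved(tabs$afReported), solved(tabs$afNovel))
  af_fail <- rbind(tabs$ditReported[tabs$ditReported$af_failed, ],
                   tabs$ditNovel[tabs$ditNovel$af_failed, ])
  af <- rbind(af, failed(af_fail$uniprot, af_fail$gene))
  ns_af <- tabs$noSolution[tabs$noSolution$source == "AF", ]
  af <- rbind(af, failed(ns_af$uniprot, ns_af$gene))

  dit <- rbind(solved(tabs$ditReported[, names(tabs$ditReported) !=
                                         "af_failed"]),
               solved(tabs$ditNovel[, names(tabs$ditNovel) != "af_failed"]))
  ns_dit <- tabs$noSolution[tabs$noSolution$source == "DIT", ]
  dit <- rbind(dit, failed(ns_dit$uniprot, ns_dit$gene))

  stopifnot(!anyDuplicated(af$uniprot), !anyDuplicated(dit$uniprot))
  list(af = af, dit = dit)
}
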