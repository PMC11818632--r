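#' Interacting-region definitions
#'
#' \code{IRDefinition()} builds a definition from name/start/end vectors;
#' \code{readIRDefinition()} reads the TSV dialect \code{name, start, end};
#' \code{syntheticIRDefinition()} builds an unnamed definition from
#' start/end vectors for synthetic tests. The packaged default layout
#' (\code{system.file("extdata", "ir_synthetic.tsv", package = "p2dock")})
#' is a documented synthetic placeholder of five regions totalling 61
#' residues on a 361-residue receptor, matching the scale of the ataxin-3
#' IR set; real analyses must supply the receptor's own IR coordinates.
#'
#' @param name,start,end region names and inclusive residue bounds.
#' @param path TSV file with columns \code{name}, \code{start}, \code{end}.
#' @return an [IRDefinition-class].
#' @export
IRDefinition <- function(name, start, end) {
  new("IRDefinition", regions = data.frame(
    name = as.character(name), start = as.integer(start),
    end = as.integer(end), stringsAsFactors = FALSE))
}

#' @rdname IRDefinition
#' @export
readIRDefinition <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(d)))
    stop("IR definition '", path, "' needs columns name, start, end",
         call. = FALSE)
  IRDefinition(d$name, d$start, d$end)
}

#' @rdname IRDefinition
#' @export
syntheticIRDefinition <- function(start, end) {
  IRDefinition(paste0("IR", seq_along(start)), start, end)
}

#' IR coverage of a docking interface
#'
#' Scores a docking solution against the receptor's interacting regions:
#' how many IR residues are interfacing, what percentage of the IR that
#' covers, and how many receptor residues are interfacing in total.
#' Percentages are reported to 3 decimals (half-even rounding), matching
#' the reporting convention of the ataxin-3 cohort tables
#' (e.g. 44 of 61 IR residues = 72.131\%).
#'
#' @param interface an [InterfaceResult-class] computed on the receptor
#'   chain in IR numbering, or an integer vector of interfacing receptor
#'   residue numbers.
#' @param ir an [IRDefinition-class].
#' @param receptorLength optional receptor length; when given, interfacing
#'   residues outside \code{1..receptorLength} raise an error.
#' @return list with \code{irHits}, \code{irCoveragePct},
#'   \code{totalInterfacing}.
#' @examples
#' ir <- syntheticIRDefinition(c(1, 20), c(10, 29))  # 20 IR residues
#' irCoverage(c(1:5, 20:24, 100:104), ir)
#' @export
irCoverage <- function(interface, ir, receptorLength = NULL) {
  stopifnot(is(ir, "IRDefinition"))
  resno <- if (is(interface, "InterfaceResult"))
    interface@receptor$resno else as.integer(interface)
  resno <- unique(resno)
  ir_res <- irResidues(ir)
  if (!is.null(receptorLength)) {
    if (any(ir_res > receptorLength))
      stop("IR residues outside receptor range 1..", receptorLength,
           call. = FALSE)
    if (length(resno) && any(resno < 1 | resno > receptorLength))
      stop("interfacing residues outside receptor range", call. = FALSE)
  }
  hits <- length(intersect(resno, ir_res))
  list(irHits = hits,
       irCoveragePct = round(100 * hits / length(ir_res), 3),
       totalInterfacing = length(resno))
}

#' Two-stage true-interactor classification
#'
#' A candidate interactor is classified from its docking records against
#' alternative predicted receptor/ligand structures: if the AlphaFold-based
#' record exists, produced a docking solution, and covers strictly more
#' than \code{threshold} percent of the IR residues, the protein is a true
#' interactor on AlphaFold evidence (\code{TRUE_INTERACTOR_AF}); otherwise
#' the D-I-TASSER-based record is consulted the same way
#' (\code{TRUE_INTERACTOR_DIT}); if neither source produced a docking
#' solution the verdict is \code{NO_SOLUTION}; otherwise
#' \code{NOT_SUPPORTED}. The inequality is strict: coverage 50.820 passes,
#' exactly 50.000 fails.
#'
#' @param afRecord,ditRecord lists with \code{solutionFound} (logical) and
#'   \code{irCoveragePct} (percent), or \code{NULL} when no record exists
#'   for that source. At least one must be present.
#' @param threshold coverage threshold in percent (default 50).
#' @return character scalar: one of \code{"TRUE_INTERACTOR_AF"},
#'   \code{"TRUE_INTERACTOR_DIT"}, \code{"NOT_SUPPORTED"},
#'   \code{"NO_SOLUTION"}.
#' @export
classifyInteractor <- function(afRecord = NULL, ditRecord = NULL,
                               threshold = 50) {
  if (is.null(afRecord) && is.null(ditRecord))
    stop("at least one docking record required", call. = FALSE)
  passes <- function(r) !is.null(r) && isTRUE(r$solutionFound) &&
    isTRUE(r$irCoveragePct > threshold)
  solved <- function(r) !is.null(r) && isTRUE(r$solutionFound)
  if (passes(afRecord)) return("TRUE_INTERACTOR_AF")
  if (passes(ditRecord)) return("TRUE_INTERACTOR_DIT")
  if (!solved(afRecord) && !solved(ditRecord)) return("NO_SOLUTION")
  "NOT_SUPPORTED"
}

#' Classify a docking cohort from per-source record tables
#'
#' Applies [classifyInteractor()] to every protein of a cohort given one
#' table per structure source. Tables carry one row per protein with
#' columns \code{uniprot} (merge key), \code{gene}, \code{solution_found},
#' \code{ir_coverage_pct}; proteins may appear in either table or both.
#'
#' @param af,dit data.frames as above (either may be \code{NULL}).
#' @param threshold coverage threshold in percent (default 50).
#' @return data.frame with one row per protein: \code{uniprot},
#'   \code{gene}, \code{status}, \code{coverage} (the supporting record's
#'   coverage, \code{NA} for non-passing proteins).
#' @export
classifyCohort <- function(af = NULL, dit = NULL, threshold = 50) {
  grab <- function(d, up) {
    if (is.null(d)) return(NULL)
    i <- which(d$uniprot == up)
    if (length(i) == 0L) return(NULL)
    if (length(i) > 1L) stop("duplicate protein ", up, call. = FALSE)
    list(solutionFound = as.logical(d$solution_found[i]),
         irCoveragePct = as.numeric(d$ir_coverage_pct[i]),
         gene = d$gene[i])
  }
  ups <- unique(c(if (!is.null(af)) af$uniprot,
                  if (!is.null(dit)) dit$uniprot))
  rows <- lapply(ups, function(up) {
    a <- grab(af, up); d <- grab(dit, up)
    st <- classifyInteractor(a, d, threshold)
    cov <- if (st == "TRUE_INTERACTOR_AF") a$irCoveragePct
           else if (st == "TRUE_INTERACTOR_DIT") d$irCoveragePct
           else NA_real_
    gene <- if (!is.null(a)) a$gene else d$gene
    data.frame(uniprot = up, gene = gene, status = st, coverage = cov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise a classified cohort
#'
#' Counts per classification status and a table sorted by descending
#' supporting coverage (the cohort-table ordering convention).
#'
#' @param results data.frame from [classifyCohort()] (or any frame with
#'   \code{uniprot}, \code{status}, \code{coverage}).
#' @return list with \code{counts} (named integer vector over the four
#'   statuses), \code{nTrue} (true interactors over both sources), and
#'   \code{table} (input sorted by descending coverage).
#' @export
tabulateCohort <- function(results) {
  statuses <- c("TRUE_INTERACTOR_AF", "TRUE_INTERACTOR_DIT",
                "NOT_SUPPORTED", "NO_SOLUTION")
  if (nrow(results) == 0L)
    return(list(counts = setNames(integer(4), statuses), nTrue = 0L,
                table = results))
  if (any(duplicated(results$uniprot)))
    stop("duplicate protein(s): ",
         paste(unique(results$uniprot[duplicated(results$uniprot)]),
               collapse = ", "), call. = FALSE)
  counts <- setNames(vapply(statuses, function(s)
    sum(results$status == s), integer(1)), statuses)
  ord <- order(-ifelse(is.na(results$coverage), -Inf, results$coverage),
               results$uniprot)
  list(counts = counts,
       nTrue = unname(counts[1] + counts[2]),
       table = results[ord, , drop = FALSE])
}
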