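#' Differential interfacing statistic (expanded vs wild-type receptor)
#'
#' Percent change in the number of interfacing receptor residues between
#' the polyQ-expanded and wild-type receptor forms, relative to the
#' expanded form: \code{100 * (E - W) / E}, reported to 3 decimals
#' (half-even rounding). Positive values mean more interfacing residues
#' with the expanded form; the statistic is bounded above by 100 but has
#' no lower bound.
#'
#' @param expanded interfacing-residue count with the expanded receptor
#'   form (E, must be >= 1).
#' @param wt interfacing-residue count with the wild-type form (W, >= 0).
#' @return numeric percent difference.
#' @examples
#' differentialStat(76, 50)  # 34.211
#' differentialStat(43, 48)  # -11.628
#' @export
differentialStat <- function(expanded, wt) {
  expanded <- as.integer(expanded); wt <- as.integer(wt)
  if (any(expanded < 1))
    stop("differential statistic undefined for expanded count E = 0",
         call. = FALSE)
  if (any(wt < 0)) stop("wild-type count must be >= 0", call. = FALSE)
  round(100 * (expanded - wt) / expanded, 3)
}

.diff_categories <- c("INC_STRONG", "INC_MILD", "NONE", "DEC_MILD",
                      "DEC_STRONG")

#' Categorise a differential statistic
#'
#' Five-way banding used to colour pathway figures: strong increase
#' (\code{delta > strong}), mild increase (\code{mild < delta <= strong}),
#' none (\code{-mild <= delta <= mild}), mild decrease
#' (\code{-strong <= delta < -mild}), strong decrease
#' (\code{delta < -strong}). Defaults: strong 10, mild 5 (percent).
#' Boundary values fall in the milder band (a documented convention; no
#' observed cohort value sits exactly on a boundary).
#'
#' @param delta differential statistic(s) in percent.
#' @param strong,mild positive band edges in percent, \code{mild < strong}.
#' @return character vector over \code{INC_STRONG, INC_MILD, NONE,
#'   DEC_MILD, DEC_STRONG}.
#' @examples
#' categorizeDelta(c(34.211, 8.475, 0, -7, -40.541))
#' @export
categorizeDelta <- function(delta, strong = 10, mild = 5) {
  if (!(mild < strong)) stop("mild must be < strong", call. = FALSE)
  ifelse(delta > strong, "INC_STRONG",
  ifelse(delta > mild, "INC_MILD",
  ifelse(delta >= -mild, "NONE",
  ifelse(delta >= -strong, "DEC_MILD", "DEC_STRONG"))))
}

#' Differential table for a cohort
#'
#' Computes the differential statistic and category for a table of
#' per-protein interfacing counts.
#'
#' @param counts data.frame with columns \code{uniprot} (or any id column),
#'   \code{expanded}, \code{wt}.
#' @param strong,mild band edges forwarded to [categorizeDelta()].
#' @return the input with \code{delta_pct} and \code{category} columns
#'   appended.
#' @export
differentialTable <- function(counts, strong = 10, mild = 5) {
  stopifnot(all(c("expanded", "wt") %in% names(counts)))
  counts$delta_pct <- differentialStat(counts$expanded, counts$wt)
  counts$category <- categorizeDelta(counts$delta_pct, strong, mild)
  counts
}

#' Summarise a cohort of differential records
#'
#' Counts records per sign (positive / negative / zero differential) and
#' per category band.
#'
#' @param records data.frame with columns \code{uniprot},
#'   \code{delta_pct}, \code{category} (see [differentialTable()]).
#' @return list with \code{nPositive}, \code{nNegative}, \code{nZero} and
#'   \code{byCategory} (named integer vector over the five bands).
#' @export
cohortDifferentialSummary <- function(records) {
  if (nrow(records) == 0L)
    return(list(nPositive = 0L, nNegative = 0L, nZero = 0L,
                byCategory = setNames(integer(5), .diff_categories)))
  if (any(duplicated(records$uniprot)))
    stop("duplicate protein(s): ",
         paste(unique(records$uniprot[duplicated(records$uniprot)]),
               collapse = ", "), call. = FALSE)
  list(nPositive = sum(records$delta_pct > 0),
       nNegative = sum(records$delta_pct < 0),
       nZero = sum(records$delta_pct == 0),
       byCategory = setNames(vapply(.diff_categories, function(cc)
         sum(records$category == cc), integer(1)), .diff_categories))
}
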