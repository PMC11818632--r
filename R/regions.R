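#' Contiguous interface regions from per-residue flags
#'
#' Derives interacting regions from a per-residue interface flag vector:
#' maximal runs of flagged residues are found, runs separated by at most
#' \code{maxGap} unflagged residues are merged, and merged runs shorter
#' than \code{minLength} are discarded. Gap merging happens before length
#' filtering. Regions never start or end on an unflagged residue.
#'
#' @param flags named logical vector (names = residue numbers, contiguous)
#'   or plain logical vector (residues assumed 1..length).
#' @param minLength minimum region length in residues (>= 1, default 5).
#' @param maxGap largest unflagged gap bridged when merging (>= 0,
#'   default 1).
#' @return data.frame with columns \code{start}, \code{end} (inclusive
#'   residue numbers), sorted and non-overlapping.
#' @examples
#' f <- c(rep(TRUE, 3), FALSE, FALSE, rep(TRUE, 3))
#' findRegions(f, minLength = 5, maxGap = 2)  # one merged region 1-8
#' findRegions(f, minLength = 5, maxGap = 1)  # none survive
#' @export
findRegions <- function(flags, minLength = 5, maxGap = 1) {
  if (minLength < 1) stop("minLength must be >= 1", call. = FALSE)
  if (maxGap < 0) stop("maxGap must be >= 0", call. = FALSE)
  resno <- if (is.null(names(flags))) seq_along(flags)
           else as.integer(names(flags))
  if (length(resno) && any(diff(resno) != 1L))
    stop("residues must be contiguous in numbering", call. = FALSE)
  flags <- as.logical(flags)
  if (!any(flags))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = resno[starts[r$values]],
                     end = resno[ends[r$values]])
  # merge runs separated by <= maxGap unflagged residues
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
    if (gap <= maxGap)
      merged$end[nrow(merged)] <- runs$end[i]
    else
      merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged$end - merged$start + 1L) >= minLength
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default receptor domain annotation (ataxin-3)
#'
#' The ataxin-3 domain architecture in UniProt numbering: the catalytic
#' Josephin deubiquitinase domain (1-180), three ubiquitin-interacting
#' motifs (UIM1 224-243, UIM2 244-263, UIM3 331-349) and the
#' polyglutamine tract (292-305).
#'
#' @return data.frame with columns \code{name}, \code{start}, \code{end}.
#' @export
ataxin3Domains <- function() {
  data.frame(
    name = c("JD", "UIM1", "UIM2", "polyQ", "UIM3"),
    start = c(1L, 224L, 244L, 292L, 331L),
    end = c(180L, 243L, 263L, 305L, 349L),
    stringsAsFactors = FALSE)
}

#' Overlap of interface regions with receptor domains
#'
#' @param regions data.frame with \code{start}, \code{end} (inclusive),
#'   e.g. from [findRegions()].
#' @param domains data.frame with \code{name}, \code{start}, \code{end};
#'   default [ataxin3Domains()].
#' @return data.frame with one row per (region, overlapping domain) pair:
#'   \code{region_start}, \code{region_end}, \code{domain},
#'   \code{overlap} (residue count). Regions overlapping no domain get one
#'   row with \code{domain = NA} and \code{overlap = 0}.
#' @examples
#' annotateDomains(data.frame(start = 290, end = 300))
#' @export
annotateDomains <- function(regions, domains = ataxin3Domains()) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rs <- regions$start[i]; re <- regions$end[i]
    ov <- pmin(re, domains$end) - pmax(rs, domains$start) + 1L
    hit <- ov > 0
    if (!any(hit))
      return(data.frame(region_start = rs, region_end = re,
                        domain = NA_character_, overlap = 0L))
    data.frame(region_start = rs, region_end = re,
               domain = domains$name[hit], overlap = ov[hit])
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(region_start = integer(), region_end = integer(),
                         domain = character(), overlap = integer())
  rownames(out) <- NULL
  out
}

#' Write a viewer highlight annotation table
#'
#' Emits a generic residue-range annotation table
#' (\code{chain,start,end,label,color}, comma-separated) consumable by
#' molecular viewers; rows are ordered by region start so output is
#' deterministic.
#'
#' @param regions data.frame with \code{start}, \code{end}.
#' @param path output file.
#' @param chain chain identifier written on every row (default "A").
#' @param labelPrefix region label prefix (default "region").
#' @param color colour token (default "red").
#' @return \code{path}, invisibly.
#' @export
writeHighlightTable <- function(regions, path, chain = "A",
                                labelPrefix = "region", color = "red") {
  ord <- order(regions$start)
  tab <- data.frame(
    chain = rep(chain, nrow(regions)),
    start = regions$start[ord], end = regions$end[ord],
    label = if (nrow(regions)) paste0(labelPrefix, seq_len(nrow(regions)))
            else character(),
    color = rep(color, nrow(regions)))
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHighlightTable
#' @export
readHighlightTable <- function(path) {
  read.delim(path, sep = ",", stringsAsFactors = FALSE)
}
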