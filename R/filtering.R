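#' Read / write a protein identifier list
#'
#' One protein per line: \code{GeneSymbol<TAB>UniProt<TAB>GeneID}. The
#' UniProt accession is the identity key throughout; gene symbols are
#' display-only.
#'
#' @param path file path.
#' @return data.frame with columns \code{gene}, \code{uniprot},
#'   \code{gene_id}.
#' @export
readProteinList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop("unparseable identifier line ", bad[1], " in '", path,
         "': expected GeneSymbol<TAB>UniProt<TAB>GeneID", call. = FALSE)
  d <- data.frame(gene = vapply(parts, `[`, "", 1),
                  uniprot = vapply(parts, `[`, "", 2),
                  gene_id = as.integer(vapply(parts, `[`, "", 3)),
                  stringsAsFactors = FALSE)
  ok <- grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$|^[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}$",
              d$uniprot)
  if (any(!ok))
    stop("invalid UniProt accession(s) in '", path, "': ",
         paste(d$uniprot[!ok], collapse = ", "), call. = FALSE)
  d
}

#' @rdname readProteinList
#' @param proteins data.frame as returned by \code{readProteinList}.
#' @export
writeProteinList <- function(proteins, path) {
  writeLines(paste(proteins$gene, proteins$uniprot, proteins$gene_id,
                   sep = "\t"), path)
  invisible(path)
}

.dedup <- function(d, label) {
  dup <- duplicated(d$uniprot)
  if (any(dup)) {
    warning("duplicate identifier(s) collapsed in ", label, ": ",
            paste(unique(d$uniprot[dup]), collapse = ", "), call. = FALSE)
    d <- d[!dup, , drop = FALSE]
  }
  d
}

#' Set operations on protein lists
#'
#' Set semantics keyed on UniProt accession, preserving the stable order of
#' the first list; duplicates collapse with a warning.
#'
#' @param a,b protein list data.frames (see [readProteinList()]).
#' @return a filtered protein list data.frame.
#' @export
intersectProteins <- function(a, b) {
  a <- .dedup(a, "first list"); b <- .dedup(b, "second list")
  out <- a[a$uniprot %in% b$uniprot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname intersectProteins
#' @export
excludeProteins <- function(a, b) {
  a <- .dedup(a, "first list"); b <- .dedup(b, "second list")
  out <- a[!a$uniprot %in% b$uniprot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a tissue expression table
#'
#' TSV with columns \code{gene} (identifier matching the protein list's
#' UniProt or gene symbol), \code{tissue}, \code{level}. A protein counts
#' as expressed in a tissue when its level is nonzero / "detected" (any
#' value other than 0, "0", "", "nd", "not detected").
#'
#' @param path TSV file.
#' @return data.frame with \code{gene}, \code{tissue}, \code{level} and a
#'   logical \code{detected} column.
#' @export
readExpressionTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "tissue", "level") %in% names(d)))
    stop("expression table '", path, "' needs columns gene, tissue, level",
         call. = FALSE)
  if (any(duplicated(paste(d$gene, d$tissue, sep = "\r"))))
    stop("duplicate (gene, tissue) pair(s) in expression table",
         call. = FALSE)
  lvl <- tolower(trimws(as.character(d$level)))
  d$detected <- !(lvl %in% c("0", "", "nd", "not detected"))
  suppressWarnings({
    num <- as.numeric(lvl)
    d$detected[!is.na(num)] <- num[!is.na(num)] > 0
  })
  d
}

#' Filter proteins by tissue expression
#'
#' Keeps proteins detected in all (default) or any of the listed tissues,
#' e.g. the seven SCA3/MJD-relevant brain tissues (cerebral cortex, basal
#' ganglia, thalamus, midbrain, pons, medulla oblongata, cerebellum).
#'
#' @param proteins protein list data.frame (see [readProteinList()]).
#' @param expression expression table (see [readExpressionTable()]); the
#'   \code{gene} column may hold UniProt accessions or gene symbols.
#' @param tissues nonempty character vector of tissue names.
#' @param requireAll keep only proteins detected in every listed tissue
#'   (default TRUE); FALSE keeps proteins detected in at least one.
#' @return the filtered protein list (a subset of \code{proteins}, original
#'   order preserved).
#' @export
expressionFilter <- function(proteins, expression, tissues,
                             requireAll = TRUE) {
  if (length(tissues) == 0L) stop("tissues must be nonempty", call. = FALSE)
  avail <- unique(expression$tissue)
  miss <- setdiff(tissues, avail)
  if (length(miss))
    stop("tissue(s) absent from table: ", paste(miss, collapse = ", "),
         "; available: ", paste(sort(avail), collapse = ", "),
         call. = FALSE)
  ex <- expression[expression$tissue %in% tissues & expression$detected, ,
                   drop = FALSE]
  n_detected <- function(id1, id2) {
    length(unique(ex$tissue[ex$gene == id1 | ex$gene == id2]))
  }
  need <- if (requireAll) length(tissues) else 1L
  keep <- mapply(n_detected, proteins$uniprot, proteins$gene) >= need
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
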