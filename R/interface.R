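#' Interfacing residues of a docked two-chain complex
#'
#' Determines which residues of each chain form the complex interface,
#' either thermodynamically (buried solvent-accessible surface area,
#' \code{mode = "dsasa"}) or geometrically (heavy-atom distance cutoff,
#' \code{mode = "distance"}).
#'
#' In \code{dsasa} mode a residue is interfacing iff its SASA computed on
#' the isolated chain minus its SASA in the complex exceeds \code{bsaMin};
#' the per-residue difference is reported as buried area (BSA). In
#' \code{distance} mode a residue is interfacing iff any of its heavy atoms
#' lies within \code{contactCutoff} of any atom of the partner chain (no
#' areas are computed; \code{bsa} is \code{NA}).
#'
#' @param complex a two-chain (or more) [StructureModel-class]; only the two
#'   named chains are considered.
#' @param receptorChain,ligandChain chain identifiers (must differ).
#' @param mode \code{"dsasa"} or \code{"distance"}.
#' @param bsaMin minimum buried area per residue, Angstrom^2 (default 0.1;
#'   interface callers conventionally use "any burial > 0").
#' @param contactCutoff heavy-atom contact distance in Angstrom
#'   (default 5.0).
#' @param probeRadius,nSpherePoints forwarded to [computeSasa()].
#' @return an [InterfaceResult-class].
#' @examples
#' ir <- syntheticIRDefinition(c(3, 10), c(6, 13))
#' cx <- makeToyComplex(seed = 3, receptorLength = 20, ir = ir,
#'                      plantedIrHits = 4, plantedExtraContacts = 2)
#' findInterfaceResidues(cx, "A", "B", mode = "dsasa")
#' @export
findInterfaceResidues <- function(complex, receptorChain, ligandChain,
                                  mode = c("dsasa", "distance"),
                                  bsaMin = 0.1, contactCutoff = 5.0,
                                  probeRadius = 1.4, nSpherePoints = 960) {
  stopifnot(is(complex, "StructureModel"))
  mode <- match.arg(mode)
  if (identical(receptorChain, ligandChain))
    stop("receptor and ligand chains must differ", call. = FALSE)
  present <- chainIds(complex)
  if (length(present) < 2L)
    stop("a docked complex needs at least two chains", call. = FALSE)
  miss <- setdiff(c(receptorChain, ligandChain), present)
  if (length(miss))
    stop("chain(s) not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)

  a <- complex@atoms
  a <- a[a$chain %in% c(receptorChain, ligandChain), , drop = FALSE]
  pair <- new("StructureModel", atoms = a, source = complex@source)

  one_side <- function(chain) {
    if (mode == "dsasa") {
      iso <- computeSasa(pair, probeRadius, nSpherePoints, chains = chain)
      cpx <- computeSasa(pair, probeRadius, nSpherePoints)
      cpx <- cpx[cpx$chain == chain, , drop = FALSE]
      stopifnot(identical(iso$resno, cpx$resno))
      bsa <- iso$area - cpx$area
      keep <- bsa > bsaMin
      data.frame(resno = iso$resno[keep], bsa = bsa[keep])
    } else {
      self <- a[a$chain == chain, , drop = FALSE]
      other <- a[a$chain != chain, , drop = FALSE]
      d <- .min_cross_dist(as.matrix(self[, c("x", "y", "z")]),
                           as.matrix(other[, c("x", "y", "z")]))
      resno <- sort(unique(self$resno[d <= contactCutoff]))
      data.frame(resno = resno, bsa = rep(NA_real_, length(resno)))
    }
  }

  new("InterfaceResult",
      receptorChain = receptorChain, ligandChain = ligandChain,
      receptor = one_side(receptorChain), ligand = one_side(ligandChain),
      method = if (mode == "dsasa") "DELTA_SASA" else "DISTANCE")
}

#' Number of interfacing receptor residues
#' @param x an [InterfaceResult-class].
#' @return integer count, equal to \code{nrow(receptorInterfacing(x))}.
#' @export
receptorTotalCount <- function(x) {
  stopifnot(is(x, "InterfaceResult"))
  nrow(x@receptor)
}

#' Write an interface result as a per-residue TSV
#'
#' Columns \code{chain}, \code{resno}, \code{role} (receptor/ligand) and
#' \code{bsa}; stable ordering (receptor first, then ligand, by residue
#' number).
#' @param x an [InterfaceResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeInterfaceTable <- function(x, path) {
  stopifnot(is(x, "InterfaceResult"))
  tab <- rbind(
    data.frame(chain = x@receptorChain, resno = x@receptor$resno,
               role = "receptor", bsa = x@receptor$bsa),
    data.frame(chain = x@ligandChain, resno = x@ligand$resno,
               role = "ligand", bsa = x@ligand$bsa))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
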