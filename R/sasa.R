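#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with test points on a deterministic golden-section spiral,
#' so a fixed point count always yields the same areas (no RNG). Per-atom
#' areas are summed per residue.
#'
#' @param model a [StructureModel-class] (or a subset of its chains, see
#'   \code{chains}).
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, a
#'   water-sized probe).
#' @param nSpherePoints number of test points per atom (default 960;
#'   minimum 60). More points = smoother areas, linearly slower.
#' @param chains optional character vector restricting the calculation to
#'   those chains *in isolation* (other chains are removed before the
#'   calculation, they do not occlude).
#' @return data.frame with columns \code{chain}, \code{resno}, \code{resid},
#'   \code{area} (Angstrom^2, one row per residue).
#' @examples
#' ir <- syntheticIRDefinition(5, 8)
#' m <- makeToyComplex(seed = 1, receptorLength = 20, ir = ir,
#'                     plantedIrHits = 2)
#' head(computeSasa(m))
#' @export
computeSasa <- function(model, probeRadius = 1.4, nSpherePoints = 960,
                        chains = NULL) {
  stopifnot(is(model, "StructureModel"))
  validObject(model)
  if (probeRadius <= 0) stop("probeRadius must be > 0", call. = FALSE)
  if (nSpherePoints < 60) stop("nSpherePoints must be >= 60", call. = FALSE)
  a <- model@atoms
  if (!is.null(chains)) {
    miss <- setdiff(chains, a$chain)
    if (length(miss))
      stop("no chain(s) ", paste(miss, collapse = ", "), " in model",
           call. = FALSE)
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  area <- .sasa_atoms(as.matrix(a[, c("x", "y", "z")]), a$radius,
                      probeRadius, as.integer(nSpherePoints))
  key <- paste(a$chain, a$resno, sep = "\r")
  per_res <- vapply(split(area, key), sum, numeric(1))
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resid = a$resid[first],
                    area = unname(per_res[unique(key)]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}

# Tien et al. (2013) theoretical maximum accessible areas (Gly-X-Gly),
# used to turn absolute areas into relative SASA for surface calls.
.max_acc <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Relative solvent accessibility per residue
#'
#' Absolute residue SASA divided by the residue type's theoretical maximum
#' accessible area (Gly-X-Gly reference table). Unknown residue types use
#' the table median. Values may exceed 1 for unusually exposed residues
#' (e.g. chain termini or coarse synthetic residues); callers thresholding
#' at \code{rsa >= rsaMin} are unaffected.
#'
#' @inheritParams computeSasa
#' @return the [computeSasa()] data.frame with an extra \code{rsa} column.
#' @export
relativeSasa <- function(model, probeRadius = 1.4, nSpherePoints = 960,
                         chains = NULL) {
  s <- computeSasa(model, probeRadius, nSpherePoints, chains)
  mx <- unname(.max_acc[s$resid])
  mx[is.na(mx)] <- stats::median(.max_acc)
  s$rsa <- s$area / mx
  s
}
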