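#' Heavy-atom van der Waals radii (Angstrom)
#'
#' Fixed element radius table used for all surface calculations: C 1.70,
#' N 1.55, O 1.52, S 1.80; any other heavy element falls back to 1.80.
#' Hydrogens are never modelled (predicted structures are heavy-atom only).
#' @keywords internal
.element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.default_radius <- 1.80

.radius_for <- function(element) {
  r <- unname(.element_radii[element])
  r[is.na(r)] <- .default_radius
  r
}

#' Build a StructureModel from an atom table
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{element}, \code{x}, \code{y},
#'   \code{z}; a \code{radius} column is added from the element table when
#'   absent.
#' @param source structure-source tag (\code{"ALPHAFOLD"},
#'   \code{"DITASSER"}, \code{"EXPERIMENTAL"} or \code{"SYNTHETIC"}).
#' @return a validated [StructureModel-class].
#' @export
StructureModel <- function(atoms, source = "EXPERIMENTAL") {
  if (!"radius" %in% names(atoms))
    atoms$radius <- .radius_for(atoms$element)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, source = source)
}

#' Read a PDB structure into a StructureModel
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), drops waters and
#' hydrogens, resolves alternate locations to the highest-occupancy copy,
#' and assigns element-based van der Waals radii.
#'
#' @param path path to a PDB-format text file.
#' @param source structure-source tag recorded on the model.
#' @return a [StructureModel-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeStructure(makeToyComplex(seed = 1, receptorLength = 30,
#'   ir = syntheticIRDefinition(c(5, 10), c(8, 12)), plantedIrHits = 2), pdb)
#' readStructure(pdb, source = "SYNTHETIC")
#' @export
readStructure <- function(path, source = "EXPERIMENTAL") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("unparseable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  # drop waters and hydrogens
  a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  elem <- a$elesy
  no_elem <- is.na(elem) | !nzchar(trimws(elem))
  elem[no_elem] <- substr(gsub("^[0-9]*", "", trimws(a$elety[no_elem])), 1, 1)
  elem <- toupper(trimws(elem))
  a <- a[elem != "H" & elem != "D", , drop = FALSE]
  elem <- elem[elem != "H" & elem != "D"]
  if (nrow(a) == 0L)
    stop("empty model: '", path, "' contains no heavy protein atoms",
         call. = FALSE)
  # alternate locations: keep the highest-occupancy copy per atom site
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- a$o
    occ[is.na(occ)] <- 1
    key <- paste(a$chain, a$resno, a$elety, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    keep <- sort(keep)
    a <- a[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  ch <- a$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  StructureModel(data.frame(
    chain = ch, resno = as.integer(a$resno), resid = a$resid,
    elety = a$elety, element = elem,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE), source = source)
}

#' Write a StructureModel to a PDB file
#'
#' Emits ATOM records with TER-terminated chains;
#' \code{readStructure(writeStructure(m))} reproduces the modelled chain,
#' residue and atom content.
#'
#' @param model a [StructureModel-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  validObject(model)
  a <- model@atoms
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("unwritable path: ", path, call. = FALSE)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   chainter = TRUE)
  invisible(path)
}

#' Shift residue numbering of one chain
#'
#' Maps a chain onto a reference numbering (e.g. UniProt coordinates) by a
#' constant offset, so interface residues can be compared against IR
#' definitions expressed in reference numbering.
#'
#' @param model a [StructureModel-class].
#' @param chain chain identifier to renumber.
#' @param offset integer added to every residue number of that chain.
#' @return a new [StructureModel-class]; residue order is preserved.
#' @export
renumberToReference <- function(model, chain, offset) {
  stopifnot(is(model, "StructureModel"))
  if (!chain %in% model@atoms$chain)
    stop("no chain '", chain, "' in model", call. = FALSE)
  offset <- as.integer(offset)
  a <- model@atoms
  sel <- a$chain == chain
  a$resno[sel] <- a$resno[sel] + offset
  out <- new("StructureModel", atoms = a, source = model@source)
  validObject(out)  # catches collisions after the shift
  out
}
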