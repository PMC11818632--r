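#' Read a PISA-style interface XML report
#'
#' Parses the interface XML subset emitted by macromolecular interface
#' analysis services: an \code{<interface>} element containing
#' \code{<molecule>} elements (one per chain), each with \code{<residue>}
#' children carrying \code{<ser_no>}, \code{<seq_num>}, \code{<name>},
#' \code{<asa>} and \code{<bsa>}. Residues with buried area
#' (\code{bsa > 0}) on the receptor molecule become the receptor
#' interfacing set, and likewise for the remaining (ligand) molecule.
#'
#' @param path XML file path.
#' @param receptorChain chain identifier of the receptor molecule.
#' @return an [InterfaceResult-class] with method \code{"PISA_XML"}.
#' @seealso [writePisaInterfaceXml()] for the matching writer.
#' @export
readPisaInterfaceXml <- function(path, receptorChain) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed interface XML '", path, "': ", conditionMessage(e),
         call. = FALSE))
  mols <- xml2::xml_find_all(doc, ".//molecule")
  if (length(mols) == 0L)
    stop("malformed interface XML: no <molecule> elements under ",
         xml2::xml_name(doc), call. = FALSE)
  chain_of <- vapply(mols, function(m)
    xml2::xml_text(xml2::xml_find_first(m, "./chain_id")), character(1))
  if (!receptorChain %in% chain_of)
    stop("no <molecule> with chain_id '", receptorChain,
         "' in interface XML (found: ", paste(chain_of, collapse = ", "),
         ")", call. = FALSE)
  residues_of <- function(mol) {
    rs <- xml2::xml_find_all(mol, ".//residue")
    num <- function(xp) as.numeric(vapply(rs, function(r)
      xml2::xml_text(xml2::xml_find_first(r, xp)), character(1)))
    resno <- num("./seq_num")
    bsa <- num("./bsa")
    if (any(is.na(resno)) || any(is.na(bsa)))
      stop("malformed interface XML: residue without <seq_num> or <bsa> ",
           "under molecule/residues", call. = FALSE)
    keep <- bsa > 0
    data.frame(resno = as.integer(resno[keep]), bsa = bsa[keep])
  }
  rec_idx <- which(chain_of == receptorChain)[1L]
  lig_idx <- setdiff(seq_along(mols), rec_idx)[1L]
  if (is.na(lig_idx))
    stop("interface XML has a single molecule; two chains expected",
         call. = FALSE)
  new("InterfaceResult",
      receptorChain = receptorChain, ligandChain = chain_of[lig_idx],
      receptor = residues_of(mols[[rec_idx]]),
      ligand = residues_of(mols[[lig_idx]]),
      method = "PISA_XML")
}

#' Write an InterfaceResult as PISA-style interface XML
#'
#' Emits the same XML subset [readPisaInterfaceXml()] consumes, so native
#' interface results can be round-tripped through the XML path. Accessible
#' areas are written as 0 (not modelled in this subset); buried areas come
#' from the result (1.0 for distance-mode results, which carry no areas).
#'
#' @param x an [InterfaceResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePisaInterfaceXml <- function(x, path) {
  stopifnot(is(x, "InterfaceResult"))
  doc <- xml2::xml_new_root("interface")
  add_mol <- function(chain, tab) {
    mol <- xml2::xml_add_child(doc, "molecule")
    xml2::xml_add_child(mol, "chain_id", chain)
    rs <- xml2::xml_add_child(mol, "residues")
    for (i in seq_len(nrow(tab))) {
      r <- xml2::xml_add_child(rs, "residue")
      xml2::xml_add_child(r, "ser_no", as.character(i))
      xml2::xml_add_child(r, "seq_num", as.character(tab$resno[i]))
      xml2::xml_add_child(r, "name", "UNK")
      xml2::xml_add_child(r, "asa", "0.000")
      bsa <- tab$bsa[i]
      if (is.na(bsa)) bsa <- 1.0
      xml2::xml_add_child(r, "bsa", sprintf("%.3f", bsa))
    }
  }
  add_mol(x@receptorChain, x@receptor)
  add_mol(x@ligandChain, x@ligand)
  xml2::write_xml(doc, path)
  invisible(path)
}
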