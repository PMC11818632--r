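#' Accessors for p2dock S4 objects
#'
#' Small accessor generics: slot access is never part of the public
#' interface.
#'
#' @param x an object of the documented class.
#' @return \code{atoms()}: the atom data.frame of a [StructureModel-class];
#'   \code{chainIds()}: character vector of chain identifiers;
#'   \code{sourceTag()}: the structure-source tag;
#'   \code{residueNumbers()}: integer residue numbers of one chain;
#'   \code{receptorInterfacing()}/\code{ligandInterfacing()}: per-residue
#'   interface tables (\code{resno}, \code{bsa}) of an
#'   [InterfaceResult-class]; \code{interfaceMethod()}: detection method;
#'   \code{irRegions()}: region table of an [IRDefinition-class];
#'   \code{irResidues()}: all IR residue numbers; \code{irTotalResidues()}:
#'   their count; \code{activeResidues()}/\code{passiveResidues()}: restraint
#'   sets; \code{pipelineStages()}/\code{pipelineConfig()}: stage table and
#'   config map of a [PipelineSpec-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("sourceTag", function(x) standardGeneric("sourceTag"))
#' @rdname accessors
#' @param chain single-character chain identifier.
#' @export
setGeneric("residueNumbers",
           function(x, chain) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setGeneric("receptorInterfacing",
           function(x) standardGeneric("receptorInterfacing"))
#' @rdname accessors
#' @export
setGeneric("ligandInterfacing",
           function(x) standardGeneric("ligandInterfacing"))
#' @rdname accessors
#' @export
setGeneric("interfaceMethod", function(x) standardGeneric("interfaceMethod"))
#' @rdname accessors
#' @export
setGeneric("irRegions", function(x) standardGeneric("irRegions"))
#' @rdname accessors
#' @export
setGeneric("irResidues", function(x) standardGeneric("irResidues"))
#' @rdname accessors
#' @export
setGeneric("irTotalResidues", function(x) standardGeneric("irTotalResidues"))
#' @rdname accessors
#' @export
setGeneric("activeResidues", function(x) standardGeneric("activeResidues"))
#' @rdname accessors
#' @export
setGeneric("passiveResidues", function(x) standardGeneric("passiveResidues"))
#' @rdname accessors
#' @export
setGeneric("pipelineStages", function(x) standardGeneric("pipelineStages"))
#' @rdname accessors
#' @export
setGeneric("pipelineConfig", function(x) standardGeneric("pipelineConfig"))

#' @rdname accessors
setMethod("atoms", "StructureModel", function(x) x@atoms)
#' @rdname accessors
setMethod("chainIds", "StructureModel",
          function(x) unique(x@atoms$chain))
#' @rdname accessors
setMethod("sourceTag", "StructureModel", function(x) x@source)
#' @rdname accessors
setMethod("residueNumbers", "StructureModel", function(x, chain) {
  if (!chain %in% x@atoms$chain)
    stop("no chain '", chain, "' in model", call. = FALSE)
  unique(x@atoms$resno[x@atoms$chain == chain])
})

#' @rdname accessors
setMethod("receptorInterfacing", "InterfaceResult", function(x) x@receptor)
#' @rdname accessors
setMethod("ligandInterfacing", "InterfaceResult", function(x) x@ligand)
#' @rdname accessors
setMethod("interfaceMethod", "InterfaceResult", function(x) x@method)

#' @rdname accessors
setMethod("irRegions", "IRDefinition", function(x) x@regions)
#' @rdname accessors
setMethod("irResidues", "IRDefinition", function(x)
  as.integer(unlist(Map(seq.int, x@regions$start, x@regions$end))))
#' @rdname accessors
setMethod("irTotalResidues", "IRDefinition",
          function(x) length(irResidues(x)))

#' @rdname accessors
setMethod("activeResidues", "RestraintSet", function(x) x@active)
#' @rdname accessors
setMethod("passiveResidues", "RestraintSet", function(x) x@passive)

#' @rdname accessors
setMethod("pipelineStages", "PipelineSpec", function(x) x@stages)
#' @rdname accessors
setMethod("pipelineConfig", "PipelineSpec", function(x) x@config)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cc <- table(factor(a$chain, levels = unique(a$chain)))
  nres <- vapply(names(cc), function(ch)
    length(unique(a$resno[a$chain == ch])), integer(1))
  cat(sprintf("StructureModel [%s]: %d chain(s), %d residues, %d heavy atoms\n",
              object@source, length(cc), sum(nres), nrow(a)))
  for (ch in names(cc))
    cat(sprintf("  chain %s: %d residues, %d atoms\n", ch, nres[[ch]], cc[[ch]]))
})

setMethod("show", "InterfaceResult", function(object) {
  cat(sprintf("InterfaceResult (%s): receptor chain %s, ligand chain %s\n",
              object@method, object@receptorChain, object@ligandChain))
  cat(sprintf("  receptor interfacing residues: %d\n", nrow(object@receptor)))
  cat(sprintf("  ligand interfacing residues:   %d\n", nrow(object@ligand)))
})

setMethod("show", "IRDefinition", function(object) {
  r <- object@regions
  cat(sprintf("IRDefinition: %d region(s), %d residues total\n",
              nrow(r), irTotalResidues(object)))
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s: %d-%d (%d residues)\n", r$name[i], r$start[i],
                r$end[i], r$end[i] - r$start[i] + 1L))
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d active, %d passive residues\n",
              length(object@active), length(object@passive)))
})

setMethod("show", "PipelineSpec", function(object) {
  s <- object@stages
  cat(sprintf("PipelineSpec '%s': %d stage(s)\n", object@project, nrow(s)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %d. %s: %s -> %s%s\n", i, s$module[i], s$input[i],
                s$output[i],
                if (is.na(s$block[i])) "" else sprintf(" [block %d]", s$block[i])))
  if (length(object@config))
    cat(sprintf("  config: %d variable(s)\n", length(object@config)))
})
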