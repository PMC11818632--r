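#' Class \code{StructureModel}: heavy-atom model of a (possibly docked) protein
#'
#' Container for the residue/atom model all geometric operations use. Atoms
#' are stored as a data.frame with one row per heavy atom and columns
#' \code{chain} (single character), \code{resno} (author residue number,
#' integer), \code{resid} (3-letter residue name), \code{elety} (atom name),
#' \code{element} (element symbol), \code{x}, \code{y}, \code{z}
#' (coordinates, Angstrom) and \code{radius} (van der Waals radius,
#' Angstrom).
#'
#' @slot atoms data.frame of heavy atoms as described above.
#' @slot source character scalar, one of \code{"ALPHAFOLD"},
#'   \code{"DITASSER"}, \code{"EXPERIMENTAL"}, \code{"SYNTHETIC"}.
#'
#' @seealso [readStructure()], [writeStructure()], [makeToyComplex()]
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character"),
  prototype(source = "EXPERIMENTAL"))

.structure_sources <- c("ALPHAFOLD", "DITASSER", "EXPERIMENTAL", "SYNTHETIC")

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "element",
            "x", "y", "z", "radius")
  msgs <- character()
  if (!all(need %in% names(a)))
    msgs <- c(msgs, paste("atoms must have columns:",
                          paste(setdiff(need, names(a)), collapse = ", ")))
  else {
    if (nrow(a) == 0L)
      msgs <- c(msgs, "empty model: no heavy atoms")
    if (nrow(a) > 0L) {
      if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
        msgs <- c(msgs, "non-finite atom coordinates")
      if (!all(a$radius > 0))
        msgs <- c(msgs, "atom radii must be positive")
      # residue numbers strictly ordered and unique within each chain
      for (ch in unique(a$chain)) {
        rn <- unique(a$resno[a$chain == ch])
        if (any(duplicated(rn)))
          msgs <- c(msgs, sprintf("duplicate residue numbers in chain %s", ch))
        if (is.unsorted(rn))
          msgs <- c(msgs, sprintf("residues of chain %s not ordered by number", ch))
      }
    }
  }
  if (length(object@source) != 1L || !object@source %in% .structure_sources)
    msgs <- c(msgs, paste("source must be one of",
                          paste(.structure_sources, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Class \code{InterfaceResult}: interfacing residues of a docked complex
#'
#' Per-chain interfacing residue sets of a two-chain docked complex, with
#' per-residue buried surface area (BSA, Angstrom^2) where the detection
#' method provides one.
#'
#' @slot receptorChain,ligandChain single-character chain identifiers.
#' @slot receptor,ligand data.frames with columns \code{resno} and
#'   \code{bsa} (buried area; \code{NA} allowed for distance mode rows only
#'   when the method computes no areas).
#' @slot method one of \code{"DELTA_SASA"}, \code{"DISTANCE"},
#'   \code{"PISA_XML"}.
#'
#' @seealso [findInterfaceResidues()], [readPisaInterfaceXml()]
#' @export
setClass("InterfaceResult",
  representation(receptorChain = "character", ligandChain = "character",
                 receptor = "data.frame", ligand = "data.frame",
                 method = "character"))

.interface_methods <- c("DELTA_SASA", "DISTANCE", "PISA_XML")

setValidity("InterfaceResult", function(object) {
  msgs <- character()
  ok_tab <- function(d, lab) {
    m <- character()
    if (!all(c("resno", "bsa") %in% names(d)))
      m <- c(m, sprintf("%s table needs columns resno, bsa", lab))
    else {
      if (any(duplicated(d$resno)))
        m <- c(m, sprintf("duplicate residue numbers in %s set", lab))
      if (any(!is.na(d$bsa) & d$bsa <= 0))
        m <- c(m, sprintf("%s buried areas must be > 0", lab))
    }
    m
  }
  msgs <- c(msgs, ok_tab(object@receptor, "receptor"),
            ok_tab(object@ligand, "ligand"))
  if (length(object@method) != 1L || !object@method %in% .interface_methods)
    msgs <- c(msgs, paste("method must be one of",
                          paste(.interface_methods, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Class \code{IRDefinition}: interacting regions of a receptor
#'
#' Named, non-overlapping residue ranges (inclusive) defining the receptor's
#' interacting regions (IRs), e.g. the five ataxin-3 IRs totalling 61
#' residues against which docking solutions are scored.
#'
#' @slot regions data.frame with columns \code{name}, \code{start},
#'   \code{end} (inclusive residue numbers).
#'
#' @seealso [irCoverage()], [readIRDefinition()], [syntheticIRDefinition()]
#' @export
setClass("IRDefinition", representation(regions = "data.frame"))

setValidity("IRDefinition", function(object) {
  r <- object@regions
  msgs <- character()
  if (!all(c("name", "start", "end") %in% names(r)))
    return("regions must have columns name, start, end")
  if (nrow(r) == 0L) msgs <- c(msgs, "at least one region required")
  if (any(r$end < r$start)) msgs <- c(msgs, "region end before start")
  res <- unlist(Map(seq.int, r$start, r$end))
  if (any(duplicated(res))) msgs <- c(msgs, "regions overlap")
  if (any(duplicated(r$name))) msgs <- c(msgs, "duplicate region names")
  if (length(msgs)) msgs else TRUE
})

#' Class \code{RestraintSet}: active and passive docking restraint residues
#'
#' Active residues drive ambiguous interaction restraints during docking;
#' passive residues are permitted to participate. The two sets are disjoint.
#'
#' @slot active,passive integer vectors of residue numbers.
#'
#' @seealso [consensusActive()], [passiveFromActive()], [writeRestraints()]
#' @export
setClass("RestraintSet",
  representation(active = "integer", passive = "integer"))

setValidity("RestraintSet", function(object) {
  msgs <- character()
  if (length(intersect(object@active, object@passive)))
    msgs <- c(msgs, "active and passive sets must be disjoint")
  if (any(duplicated(object@active)) || any(duplicated(object@passive)))
    msgs <- c(msgs, "duplicate residue numbers in a restraint set")
  if (length(msgs)) msgs else TRUE
})

#' Class \code{PipelineSpec}: a validated analysis pipeline
#'
#' Ordered stages (module, input folder, output folder, optional per-ligand
#' block size) plus a configuration map of module-prefixed variables.
#'
#' @slot stages data.frame with columns \code{module}, \code{input},
#'   \code{output}, \code{block} (integer, \code{NA} when absent).
#' @slot config named character vector of \code{key=value} settings.
#' @slot project character scalar, project folder name.
#'
#' @seealso [parsePipeline()], [runPipeline()], [drawPipeline()]
#' @export
setClass("PipelineSpec",
  representation(stages = "data.frame", config = "character",
                 project = "character"),
  prototype(project = "project"))

setValidity("PipelineSpec", function(object) {
  s <- object@stages
  msgs <- character()
  if (!all(c("module", "input", "output", "block") %in% names(s)))
    return("stages must have columns module, input, output, block")
  if (nrow(s) == 0L) msgs <- c(msgs, "pipeline has no stages")
  bad <- !s$module %in% registeredModules()
  if (any(bad))
    msgs <- c(msgs, sprintf("unknown module name(s): %s (line %s)",
                            paste(s$module[bad], collapse = ", "),
                            paste(which(bad), collapse = ", ")))
  if (any(duplicated(s$output)))
    msgs <- c(msgs, sprintf("duplicate output folder(s): %s",
                            paste(unique(s$output[duplicated(s$output)]),
                                  collapse = ", ")))
  bad_name <- function(x) !nzchar(x) | grepl("[/\\\\]", x)
  if (any(bad_name(s$input)) || any(bad_name(s$output)))
    msgs <- c(msgs, "folder names must be nonempty and contain no path separators")
  blk <- s$block
  if (any(!is.na(blk) & blk < 1L))
    msgs <- c(msgs, "block sizes must be integers >= 1")
  over <- which(!is.na(blk) & seq_len(nrow(s)) + blk - 1L > nrow(s))
  if (length(over))
    msgs <- c(msgs, sprintf("block at stage %s extends past the last stage",
                            paste(over, collapse = ", ")))
  # an input produced only by a later stage is dangling at the time it is
  # consumed; folders never produced at all are initial external inputs,
  # whose existence is checked against the workdir at run time
  for (i in seq_len(nrow(s))) {
    before <- s$output[seq_len(i - 1L)]
    later <- s$output[setdiff(seq_len(nrow(s)), seq_len(i))]
    if (s$input[i] %in% later && !s$input[i] %in% before)
      msgs <- c(msgs, sprintf(
        "stage %d consumes folder '%s' before any stage produces it", i,
        s$input[i]))
  }
  if (length(msgs)) msgs else TRUE
})
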