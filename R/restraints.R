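#' Read a per-residue interface prediction table
#'
#' One TSV per predictor: columns \code{resno}, \code{flag} (1/0 or
#' TRUE/FALSE interface call) and optionally \code{score} in [0, 1].
#'
#' @param path TSV file.
#' @param name predictor name (defaults to the file stem).
#' @return list with \code{name}, \code{resno} (integer), \code{flag}
#'   (logical), \code{score} (numeric or NULL).
#' @export
readPredictorTable <- function(path, name = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("resno", "flag") %in% names(d)))
    stop("predictor table '", path, "' needs columns resno, flag",
         call. = FALSE)
  list(name = if (is.null(name))
         tools::file_path_sans_ext(basename(path)) else name,
       resno = as.integer(d$resno),
       flag = as.logical(d$flag),
       score = if ("score" %in% names(d)) as.numeric(d$score) else NULL)
}

#' Consensus active residues from multiple interface predictors
#'
#' CPORT-style vote: a residue is active iff at least \code{minVotes}
#' predictors flag it as interface. All predictors must describe the same
#' residue range (same protein).
#'
#' @param predictions list of predictor outputs (see
#'   [readPredictorTable()]): each a list with \code{resno} and logical
#'   \code{flag}.
#' @param minVotes minimum number of agreeing predictors (default 2).
#' @return sorted integer vector of active residue numbers.
#' @export
consensusActive <- function(predictions, minVotes = 2) {
  if (length(predictions) < 1L)
    stop("at least one predictor required", call. = FALSE)
  if (minVotes < 1 || minVotes > length(predictions))
    stop("minVotes must be between 1 and the number of predictors",
         call. = FALSE)
  ranges <- lapply(predictions, function(p) sort(p$resno))
  if (!all(vapply(ranges[-1], identical, logical(1), ranges[[1]])))
    stop("predictors disagree on the protein's residue range", call. = FALSE)
  resno <- ranges[[1]]
  votes <- Reduce(`+`, lapply(predictions, function(p) {
    as.integer(p$flag[order(p$resno)])
  }))
  sort(resno[votes >= minVotes])
}

#' Passive residues around an active patch
#'
#' Standard active/passive construction for ambiguous interaction
#' restraints: passive residues are solvent-exposed residues (relative SASA
#' at least \code{rsaMin}) within \code{neighborRadius} (heavy-atom minimum
#' distance) of any active residue, minus the active set itself.
#'
#' @param model a [StructureModel-class] of the unbound monomer.
#' @param active integer vector of active residue numbers.
#' @param chain chain to operate on (default: first chain).
#' @param neighborRadius neighbourhood radius in Angstrom (default 6.5).
#' @param rsaMin relative-SASA surface threshold (default 0.15).
#' @param nSpherePoints forwarded to [relativeSasa()].
#' @return a [RestraintSet-class] combining the given active set and the
#'   derived passive set.
#' @export
passiveFromActive <- function(model, active, chain = chainIds(model)[1],
                              neighborRadius = 6.5, rsaMin = 0.15,
                              nSpherePoints = 960) {
  stopifnot(is(model, "StructureModel"))
  active <- sort(unique(as.integer(active)))
  res_all <- residueNumbers(model, chain)
  miss <- setdiff(active, res_all)
  if (length(miss))
    stop("active residue(s) not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(active) == 0L || neighborRadius <= 0)
    return(new("RestraintSet", active = active, passive = integer()))
  a <- model@atoms[model@atoms$chain == chain, , drop = FALSE]
  act_xyz <- as.matrix(a[a$resno %in% active, c("x", "y", "z")])
  d <- .min_cross_dist(as.matrix(a[, c("x", "y", "z")]), act_xyz)
  near <- sort(unique(a$resno[d <= neighborRadius]))
  rsa <- relativeSasa(model, nSpherePoints = nSpherePoints, chains = chain)
  surface <- rsa$resno[rsa$rsa >= rsaMin]
  passive <- setdiff(intersect(near, surface), active)
  new("RestraintSet", active = active, passive = as.integer(passive))
}

#' Write / read a restraint table
#'
#' Plain-text table \code{resnum<TAB>role} with role \code{active} or
#' \code{passive}; actives first, each set sorted by residue number, so
#' output is byte-stable.
#'
#' @param restraints a [RestraintSet-class].
#' @param path file path.
#' @return \code{writeRestraints}: \code{path} invisibly;
#'   \code{readRestraints}: a [RestraintSet-class].
#' @export
writeRestraints <- function(restraints, path) {
  stopifnot(is(restraints, "RestraintSet"))
  tab <- data.frame(
    resnum = c(sort(restraints@active), sort(restraints@passive)),
    role = rep(c("active", "passive"),
               c(length(restraints@active), length(restraints@passive))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRestraints
#' @export
readRestraints <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  new("RestraintSet",
      active = as.integer(d$resnum[d$role == "active"]),
      passive = as.integer(d$resnum[d$role == "passive"]))
}
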