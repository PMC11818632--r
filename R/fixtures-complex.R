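#' Synthetic docked complex with a planted interface
#'
#' Builds a deterministic toy two-chain complex for testing interface
#' detection and IR scoring. The receptor (chain A) is
#' \code{receptorLength} pseudo-residues of four backbone beads each
#' (N, CA, C, O), laid out on a self-avoiding serpentine curve with 9.5 A
#' spacing so that residues never occlude each other. The ligand (chain B)
#' places one contact residue 3.3 A above each planted receptor residue
#' and spacer residues 100 A away, so that exactly \code{plantedIrHits}
#' IR residues and \code{plantedExtraContacts} non-IR residues have
#' cross-chain heavy atoms within 4.0 A while every other receptor residue
#' stays at least 8.0 A from all ligand atoms. By construction the buried
#' surface area and distance-cutoff definitions of the interface agree
#' exactly on the planted set.
#'
#' Which IR / non-IR residues are planted is drawn with the given seed, so
#' the same spec always regenerates identical coordinates.
#'
#' @param seed integer RNG seed.
#' @param receptorLength number of receptor residues (default 361, the
#'   ataxin-3 receptor scale).
#' @param ir an [IRDefinition-class]; planted hits are sampled inside it.
#' @param plantedIrHits number of IR residues to bury (0..IR size).
#' @param plantedExtraContacts number of non-IR receptor residues to bury.
#' @return a [StructureModel-class] with source \code{"SYNTHETIC"}.
#' @examples
#' ir <- syntheticIRDefinition(c(20, 75), c(34, 88))
#' cx <- makeToyComplex(seed = 1, receptorLength = 100, ir = ir,
#'                      plantedIrHits = 10, plantedExtraContacts = 3)
#' receptorTotalCount(findInterfaceResidues(cx, "A", "B", "distance"))
#' @export
makeToyComplex <- function(seed, receptorLength = 361,
                           ir = syntheticAtaxin3IR(),
                           plantedIrHits = 0, plantedExtraContacts = 0) {
  stopifnot(is(ir, "IRDefinition"))
  ir_res <- irResidues(ir)
  if (max(ir_res) > receptorLength)
    stop("receptorLength smaller than the largest IR residue", call. = FALSE)
  if (plantedIrHits > length(ir_res))
    stop("plantedIrHits exceeds the IR residue count", call. = FALSE)
  non_ir <- setdiff(seq_len(receptorLength), ir_res)
  if (plantedExtraContacts > length(non_ir))
    stop("plantedExtraContacts exceeds the non-IR residue count",
         call. = FALSE)

  # receptor: serpentine grid, 9.5 A pitch, 4 beads per residue
  pitch <- 9.5
  ncol_grid <- ceiling(sqrt(receptorLength))
  idx <- seq_len(receptorLength) - 1L
  row <- idx %/% ncol_grid
  col_raw <- idx %% ncol_grid
  col <- ifelse(row %% 2 == 0, col_raw, ncol_grid - 1L - col_raw)
  cx <- col * pitch
  cy <- row * pitch
  bead <- data.frame(  # offsets of N, CA, C, O around the residue centre
    elety = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    dx = c(-0.8, 0, 0.8, 0), dy = c(0, 0, 0, 0.8))
  rec <- data.frame(
    chain = "A",
    resno = rep(seq_len(receptorLength), each = 4L),
    resid = "ALA",
    elety = rep(bead$elety, receptorLength),
    element = rep(bead$element, receptorLength),
    x = rep(cx, each = 4L) + rep(bead$dx, receptorLength),
    y = rep(cy, each = 4L) + rep(bead$dy, receptorLength),
    z = 0, stringsAsFactors = FALSE)

  planted <- withr::with_seed(as.integer(seed), {
    c(sort(sample(ir_res, plantedIrHits)),
      sort(sample(non_ir, plantedExtraContacts)))
  })
  planted <- sort(planted)

  lig_res <- list()
  if (length(planted)) {
    for (k in seq_along(planted)) {
      p <- planted[k]
      lig_res[[k]] <- data.frame(
        chain = "B", resno = k, resid = "GLY",
        elety = bead$elety, element = bead$element,
        x = cx[p] + bead$dx, y = cy[p] + bead$dy,
        z = c(3.3, 3.3, 3.3, 4.1), stringsAsFactors = FALSE)
    }
  }
  # spacer residues keep the ligand nonempty and give it bulk far from
  # the receptor plane
  n_spacer <- max(1L, 3L - length(planted))
  for (k in seq_len(n_spacer)) {
    lig_res[[length(lig_res) + 1L]] <- data.frame(
      chain = "B", resno = length(planted) + k, resid = "GLY",
      elety = bead$elety, element = bead$element,
      x = (k - 1L) * pitch + bead$dx, y = -100 + bead$dy,
      z = 100, stringsAsFactors = FALSE)
  }
  StructureModel(rbind(rec, do.call(rbind, lig_res)), source = "SYNTHETIC")
}

#' Synthetic five-region IR layout at the ataxin-3 scale
#'
#' A documented placeholder of five interacting regions totalling 61
#' residues on a 361-residue receptor (the published ataxin-3 IR
#' coordinates are not packaged; real analyses must supply their own).
#' Identical to the packaged \code{extdata/ir_synthetic.tsv}.
#'
#' @return an [IRDefinition-class] with 5 regions and 61 residues.
#' @export
syntheticAtaxin3IR <- function() {
  IRDefinition(paste0("IR", 1:5),
               start = c(20L, 75L, 140L, 230L, 300L),
               end = c(34L, 88L, 151L, 239L, 309L))
}

#' Synthetic noisy interface predictor outputs
#'
#' Emulates a panel of imperfect interface predictors over a protein of
#' \code{proteinLength} residues: each predictor flags each truly
#' interfacing residue with probability \code{sensitivity} and each other
#' residue with probability \code{1 - specificity}, independently across
#' predictors. Deterministic for a fixed seed.
#'
#' @param truth integer vector of truly interfacing residue numbers.
#' @param proteinLength protein length (residues 1..proteinLength).
#' @param sensitivity,specificity per-residue operating characteristics
#'   in [0, 1].
#' @param nPredictors number of predictors (default 4).
#' @param seed integer RNG seed.
#' @return list of predictor outputs, each a list with \code{name},
#'   \code{resno}, \code{flag} (see [readPredictorTable()]).
#' @export
makePredictorOutputs <- function(truth, proteinLength, sensitivity,
                                 specificity, nPredictors = 4, seed) {
  truth <- as.integer(truth)
  stopifnot(all(truth >= 1), all(truth <= proteinLength))
  is_true <- seq_len(proteinLength) %in% truth
  p_flag <- ifelse(is_true, sensitivity, 1 - specificity)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(nPredictors), function(i) {
      list(name = sprintf("predictor%d", i),
           resno = seq_len(proteinLength),
           flag = stats::runif(proteinLength) < p_flag,
           score = NULL)
    })
  })
}
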