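#' Parse and validate a pipeline and its configuration
#'
#' The pipeline dialect is line-oriented: one stage per line as
#' whitespace-separated \code{module input_folder output_folder}, with an
#' optional fourth token \code{block=N} grouping that stage and the next
#' \code{N-1} stages for per-ligand execution; \code{#} starts a comment
#' and blank lines are ignored. The config dialect is flat
#' \code{key=value} with \code{#} comments; variables prefixed with a
#' module name (e.g. \code{tabulate_ir}) are routed to that module at run
#' time. Validation is total: every malformed input yields a diagnostic
#' naming the offending line, and no partially validated spec is ever
#' returned. Branched pipelines (one stage's output consumed by several
#' later stages) are accepted.
#'
#' @param pipelineText character vector of pipeline lines (or one string
#'   with embedded newlines).
#' @param configText character vector of config lines (optional).
#' @return a validated [PipelineSpec-class].
#' @examples
#' spec <- parsePipeline(c("copy in mid", "copy mid out"),
#'                       "project=demo")
#' pipelineStages(spec)
#' @export
parsePipeline <- function(pipelineText, configText = character()) {
  plines <- unlist(strsplit(pipelineText, "\n", fixed = TRUE))
  clines <- unlist(strsplit(configText, "\n", fixed = TRUE))
  strip <- function(x) trimws(sub("#.*$", "", x))
  raw <- strip(plines)
  keep <- nzchar(raw)
  rows <- lapply(which(keep), function(i) {
    tok <- strsplit(raw[i], "[[:space:]]+")[[1]]
    block <- NA_integer_
    if (length(tok) == 4L) {
      m <- regmatches(tok[4], regexec("^block[= ]?([0-9]+)$", tok[4]))[[1]]
      if (length(m) < 2L)
        stop("pipeline line ", i, ": expected 'block=N' as fourth token, ",
             "got '", tok[4], "'", call. = FALSE)
      block <- as.integer(m[2])
      tok <- tok[1:3]
    }
    if (length(tok) != 3L)
      stop("pipeline line ", i,
           ": expected 'module input_folder output_folder [block=N]'",
           call. = FALSE)
    data.frame(module = tok[1], input = tok[2], output = tok[3],
               block = block, stringsAsFactors = FALSE)
  })
  if (!length(rows)) stop("pipeline has no stages", call. = FALSE)
  stages <- do.call(rbind, rows)

  config <- character()
  craw <- strip(clines)
  for (i in which(nzchar(craw))) {
    eq <- regexpr("=", craw[i], fixed = TRUE)
    if (eq < 2L)
      stop("config line ", i, ": expected 'key=value', got '", craw[i],
           "'", call. = FALSE)
    key <- trimws(substr(craw[i], 1, eq - 1L))
    val <- trimws(substr(craw[i], eq + 1L, nchar(craw[i])))
    config[key] <- val
  }
  project <- if ("project" %in% names(config)) config[["project"]]
             else "project"

  spec <- new("PipelineSpec", stages = stages, config = config,
              project = project)
  validObject(spec)  # module names, folder hygiene, block extents
  spec
}

#' @rdname parsePipeline
#' @param pipelinePath,configPath file paths of the pipeline and config
#'   files.
#' @export
parsePipelineFile <- function(pipelinePath, configPath = NULL) {
  parsePipeline(readLines(pipelinePath),
                if (is.null(configPath)) character()
                else readLines(configPath))
}

# module-scoped view of the config: strip the module prefix, then let a
# per-module config file from the stage's input folder win on conflict
.stage_config <- function(spec, module, input_dir = NULL) {
  cfg <- spec@config
  pref <- paste0(module, "_")
  scoped <- cfg[startsWith(names(cfg), pref)]
  names(scoped) <- substring(names(scoped), nchar(pref) + 1L)
  if (!is.null(input_dir)) {
    mod_file <- file.path(input_dir, paste0(module, ".config"))
    if (file.exists(mod_file)) {
      over <- parsePipeline("copy a b", readLines(mod_file))@config
      scoped[names(over)] <- over
    }
  }
  scoped
}

#' Expand per-ligand block groups into an execution plan
#'
#' A stage declared with \code{block=k} groups itself and the following
#' \code{k-1} stages: the group runs to completion for the first ligand
#' before starting the second, and so on. Stages outside any block run
#' once over all ligands. The multiset of (stage, ligand) work items is
#' independent of the grouping.
#'
#' @param spec a [PipelineSpec-class].
#' @param ligandIds character vector of ligand identifiers (file stems).
#' @return data.frame execution plan with columns \code{stage} (index into
#'   \code{pipelineStages(spec)}) and \code{ligand} (\code{NA} for
#'   whole-cohort stages), in execution order.
#' @examples
#' spec <- parsePipeline(c("copy a b", "copy b c block=3", "copy c d",
#'                         "copy d e", "copy e f"))
#' expandBlocks(spec, c("L1", "L2"))
#' @export
expandBlocks <- function(spec, ligandIds) {
  stopifnot(is(spec, "PipelineSpec"))
  validObject(spec)
  s <- spec@stages
  n <- nrow(s)
  grouped <- integer(0)
  plan <- list()
  i <- 1L
  while (i <= n) {
    if (!is.na(s$block[i])) {
      k <- s$block[i]
      members <- seq.int(i, i + k - 1L)
      if (any(!is.na(s$block[members[-1]])))
        stop("block starting at stage ", i,
             " overlaps another block instruction", call. = FALSE)
      if (length(ligandIds) == 0L)
        stop("block execution requires at least one ligand id",
             call. = FALSE)
      for (lig in ligandIds)
        for (m in members)
          plan[[length(plan) + 1L]] <- data.frame(stage = m, ligand = lig)
      i <- i + k
    } else {
      plan[[length(plan) + 1L]] <- data.frame(stage = i,
                                              ligand = NA_character_)
      i <- i + 1L
    }
  }
  do.call(rbind, plan)
}
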