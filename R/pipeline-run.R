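#' Execute a pipeline with provenance capture
#'
#' Stages execute in declared order inside a project folder under
#' \code{workdir}; each stage reads only its input folder and writes only
#' its output folder, and every intermediate folder persists for
#' traceability. A \code{files_to_keep} folder is populated with the
#' minimum needed to reproduce the run: the pipeline file, the config
#' file, a \code{versions.csv} provenance table (module, tool, version,
#' reference) and the terminal stages' outputs. A \code{seed} variable in
#' the config is threaded to every stage, so re-running with identical
#' inputs and config yields byte-identical \code{files_to_keep} content;
#' timestamps are confined to \code{run.log} inside the project folder.
#'
#' Stages carrying a \code{block=k} instruction run, together with the
#' following \code{k-1} stages, once per ligand (ligand identity = file
#' stem in the block's first input folder) to completion before the next
#' ligand starts.
#'
#' A stage failure halts the run with an error naming the stage; outputs
#' of completed stages remain on disk and the failure is recorded in
#' \code{error.log}.
#'
#' @param spec a validated [PipelineSpec-class].
#' @param workdir working directory holding the initial input folders.
#' @return invisibly, a list describing the provenance bundle:
#'   \code{projectDir}, \code{filesToKeepDir}, \code{versions}
#'   (data.frame).
#' @export
runPipeline <- function(spec, workdir) {
  stopifnot(is(spec, "PipelineSpec"))
  validObject(spec)
  s <- spec@stages
  n <- nrow(s)

  project_dir <- file.path(workdir, spec@project)
  keep_dir <- file.path(workdir, "files_to_keep")
  dir.create(project_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(keep_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(project_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               sprintf(...), "\n", sep = "",
                               file = log_file, append = TRUE)

  # resolve a folder name: stage output -> project dir, else initial input
  produced <- character()
  in_path <- function(name, stage_i) {
    if (name %in% produced) return(file.path(project_dir, name))
    p <- file.path(workdir, name)
    if (!dir.exists(p))
      stop("stage ", stage_i, " (", s$module[stage_i],
           "): input folder '", name,
           "' does not exist and no earlier stage produces it",
           call. = FALSE)
    p
  }

  seed <- if ("seed" %in% names(spec@config))
    as.integer(spec@config[["seed"]]) else NULL

  run_item <- function(i, ligand) {
    mod <- .module_info(s$module[i])
    inp <- in_path(s$input[i], i)
    outp <- file.path(project_dir, s$output[i])
    dir.create(outp, showWarnings = FALSE)
    cfg <- .stage_config(spec, s$module[i], input_dir = inp)
    ctx <- list(ligand = ligand, seed = seed, spec = spec)
    runner <- function() mod$fn(inp, outp, cfg, ctx)
    tryCatch({
      if (!is.null(seed)) withr::with_seed(seed + i, runner())
      else runner()
    }, error = function(e) {
      msg <- sprintf("stage %d (%s) failed: %s", i, s$module[i],
                     conditionMessage(e))
      writeLines(msg, file.path(project_dir, "error.log"))
      logline("%s", msg)
      stop(msg, call. = FALSE)
    })
    produced <<- union(produced, s$output[i])
    logline("stage %d (%s)%s done", i, s$module[i],
            if (is.na(ligand)) "" else paste0(" [", ligand, "]"))
  }

  # walk stages; ligand ids of a block are the file stems of its first
  # input folder at the time the block starts
  i <- 1L
  while (i <= n) {
    if (!is.na(s$block[i])) {
      k <- s$block[i]
      members <- seq.int(i, i + k - 1L)
      blk_in <- in_path(s$input[i], i)
      ligands <- sort(unique(tools::file_path_sans_ext(
        grep("\\.config$", list.files(blk_in), invert = TRUE,
             value = TRUE))))
      if (!length(ligands))
        stop("block execution: no ligand files found in folder '",
             s$input[i], "'", call. = FALSE)
      for (lig in ligands)
        for (m in members) run_item(m, lig)
      i <- i + k
    } else {
      run_item(i, NA_character_)
      i <- i + 1L
    }
  }

  # provenance bundle
  pipe_lines <- vapply(seq_len(n), function(i) {
    paste0(s$module[i], " ", s$input[i], " ", s$output[i],
           if (is.na(s$block[i])) "" else paste0(" block=", s$block[i]))
  }, character(1))
  writeLines(pipe_lines, file.path(keep_dir, "pipeline"))
  writeLines(if (length(spec@config))
               paste0(names(spec@config), "=", spec@config)
             else character(),
             file.path(keep_dir, "config"))

  used <- unique(s$module)
  versions <- data.frame(
    module = used,
    tool = vapply(used, function(m) .module_info(m)$tool, character(1)),
    version = as.character(utils::packageVersion("p2dock")),
    reference = vapply(used, function(m) {
      r <- .module_info(m)$reference
      if (nzchar(r)) r else "p2dock package documentation"
    }, character(1)), stringsAsFactors = FALSE)
  write.table(versions, file.path(keep_dir, "versions.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)

  # terminal outputs: folders no stage consumes
  terminal <- setdiff(s$output, s$input)
  for (tdir in terminal) {
    dest <- file.path(keep_dir, tdir)
    dir.create(dest, showWarnings = FALSE)
    for (f in list.files(file.path(project_dir, tdir), full.names = TRUE))
      file.copy(f, file.path(dest, basename(f)), overwrite = TRUE)
  }

  invisible(list(projectDir = project_dir, filesToKeepDir = keep_dir,
                 versions = versions))
}
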