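# Module registry ------------------------------------------------------
#
# Each registered module carries an executable handler plus the tool
# identity recorded in the provenance versions table. Handlers have
# signature function(input, output, cfg, ctx):
#   input/output  absolute stage folder paths
#   cfg           named character vector; module-prefixed variables arrive
#                 with the prefix stripped (e.g. tabulate_ir -> ir), and a
#                 per-module config file "<module>.config" in the input
#                 folder wins on conflict
#   ctx           list(ligand = stem or NA, seed, spec)
# Web-service and docking modules are registered as file-ingestion stubs
# that pass pre-downloaded files through, so the full published module
# vocabulary validates.

.module_registry <- new.env(parent = emptyenv())

.register_module <- function(name, fn, tool, reference = "", stub = FALSE) {
  assign(name, list(fn = fn, tool = tool, reference = reference,
                    stub = stub), envir = .module_registry)
}

#' Names of registered pipeline modules
#' @return character vector of module names accepted in pipeline files.
#' @export
registeredModules <- function() sort(ls(.module_registry))

.module_info <- function(name) get(name, envir = .module_registry)

# files of a stage input folder, optionally restricted to one ligand stem
.stage_files <- function(input, ligand = NA, pattern = NULL) {
  f <- list.files(input, full.names = TRUE, pattern = pattern)
  f <- f[!dir.exists(f)]
  f <- f[!grepl("\\.config$", f)]
  if (!is.na(ligand)) {
    stem <- tools::file_path_sans_ext(basename(f))
    f <- f[stem == ligand | startsWith(stem, paste0(ligand, "_"))]
  }
  f
}

.cfg <- function(cfg, key, default = NULL) {
  if (key %in% names(cfg)) unname(cfg[[key]]) else default
}

.mod_passthrough <- function(input, output, cfg, ctx) {
  for (f in .stage_files(input, ctx$ligand))
    file.copy(f, file.path(output, basename(f)), overwrite = TRUE)
  invisible(NULL)
}

.read_lists <- function(files) {
  lapply(files, readProteinList)
}

.mod_intersect <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, pattern = "\\.(tsv|txt)$")
  if (length(files) < 2L)
    stop("intersect needs at least two list files", call. = FALSE)
  lists <- .read_lists(files)
  out <- Reduce(intersectProteins, lists)
  writeProteinList(out, file.path(output, "intersection.tsv"))
}

.mod_exclude <- function(input, output, cfg, ctx) {
  rm_name <- .cfg(cfg, "remove")
  if (is.null(rm_name))
    stop("exclude needs config variable exclude_remove naming the list to subtract",
         call. = FALSE)
  rm_path <- file.path(input, rm_name)
  if (!file.exists(rm_path))
    stop("exclude: no file '", rm_name, "' in input folder", call. = FALSE)
  removal <- readProteinList(rm_path)
  files <- setdiff(.stage_files(input, ctx$ligand, "\\.(tsv|txt)$"), rm_path)
  for (f in files)
    writeProteinList(excludeProteins(readProteinList(f), removal),
                     file.path(output, basename(f)))
}

.mod_hpa <- function(input, output, cfg, ctx) {
  ex_name <- .cfg(cfg, "expression", "expression.tsv")
  ex_path <- file.path(input, ex_name)
  if (!file.exists(ex_path))
    stop("human_prot_atlas: no expression table '", ex_name,
         "' in input folder", call. = FALSE)
  tissues <- strsplit(.cfg(cfg, "tissues", ""), ",", fixed = TRUE)[[1]]
  tissues <- trimws(tissues[nzchar(trimws(tissues))])
  req_all <- !identical(tolower(.cfg(cfg, "require_all", "true")), "false")
  expr <- readExpressionTable(ex_path)
  files <- setdiff(.stage_files(input, ctx$ligand, "\\.(tsv|txt)$"), ex_path)
  for (f in files)
    writeProteinList(expressionFilter(readProteinList(f), expr, tissues,
                                      requireAll = req_all),
                     file.path(output, basename(f)))
}

.mod_consensus <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, "\\.tsv$")
  if (!length(files))
    stop("consensus: no predictor tables in input folder", call. = FALSE)
  preds <- lapply(files, readPredictorTable)
  mv <- as.integer(.cfg(cfg, "min_votes", "2"))
  active <- consensusActive(preds, minVotes = mv)
  writeRestraints(new("RestraintSet", active = active, passive = integer()),
                  file.path(output, "restraints.tsv"))
}

.mod_cport_like <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, "\\.tsv$")
  if (!length(files))
    stop("cport_like: no predictor tables in input folder", call. = FALSE)
  preds <- lapply(files, readPredictorTable)
  mv <- as.integer(.cfg(cfg, "min_votes", "2"))
  active <- consensusActive(preds, minVotes = mv)
  model_name <- .cfg(cfg, "model")
  rs <- if (!is.null(model_name)) {
    model <- readStructure(file.path(input, model_name))
    passiveFromActive(model, active,
                      neighborRadius = as.numeric(.cfg(cfg, "neighbor_radius", "6.5")),
                      rsaMin = as.numeric(.cfg(cfg, "rsa_min", "0.15")))
  } else new("RestraintSet", active = active, passive = integer())
  writeRestraints(rs, file.path(output, "restraints.tsv"))
}

.mod_pisa_extract <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, "\\.xml$")
  chain <- .cfg(cfg, "receptor_chain", "A")
  for (f in files) {
    res <- readPisaInterfaceXml(f, receptorChain = chain)
    writeInterfaceTable(res, file.path(
      output, paste0(tools::file_path_sans_ext(basename(f)),
                     "_interface.tsv")))
  }
}

.mod_tabulate <- function(input, output, cfg, ctx) {
  ir_name <- .cfg(cfg, "ir")
  ir <- if (is.null(ir_name)) syntheticAtaxin3IR()
        else readIRDefinition(file.path(input, ir_name))
  files <- .stage_files(input, ctx$ligand, "_interface\\.tsv$")
  rows <- lapply(files, function(f) {
    d <- read.delim(f, stringsAsFactors = FALSE)
    rec <- d$resno[d$role == "receptor"]
    cov <- irCoverage(rec, ir)
    data.frame(ligand = sub("_interface$", "",
                            tools::file_path_sans_ext(basename(f))),
               ir_coverage_pct = cov$irCoveragePct, ir_hits = cov$irHits,
               total_interfacing = cov$totalInterfacing)
  })
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(ligand = character(), ir_coverage_pct = numeric(),
                         ir_hits = integer(), total_interfacing = integer())
  tab <- tab[order(-tab$ir_coverage_pct, tab$ligand), , drop = FALSE]
  out_path <- file.path(output, "cohort.tsv")
  if (file.exists(out_path)) {  # per-ligand block runs append
    old <- read.delim(out_path, stringsAsFactors = FALSE)
    tab <- rbind(old, tab)
    tab <- tab[order(-tab$ir_coverage_pct, tab$ligand), , drop = FALSE]
  }
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.mod_get_pattern <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, "\\.tsv$")
  min_len <- as.integer(.cfg(cfg, "min_length", "5"))
  max_gap <- as.integer(.cfg(cfg, "max_gap", "1"))
  for (f in files) {
    d <- read.delim(f, stringsAsFactors = FALSE)
    if (!all(c("resno", "flag") %in% names(d))) next
    flags <- setNames(as.logical(d$flag), d$resno)
    regions <- findRegions(flags, minLength = min_len, maxGap = max_gap)
    write.table(regions, file.path(
      output, paste0(tools::file_path_sans_ext(basename(f)),
                     "_regions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

.mod_highlight <- function(input, output, cfg, ctx) {
  files <- .stage_files(input, ctx$ligand, "_regions\\.tsv$")
  chain <- .cfg(cfg, "chain", "A")
  color <- .cfg(cfg, "color", "red")
  for (f in files) {
    regions <- read.delim(f, stringsAsFactors = FALSE)
    writeHighlightTable(regions, file.path(
      output, paste0(sub("_regions$", "",
                         tools::file_path_sans_ext(basename(f))),
                     "_highlight.csv")),
      chain = chain, color = color)
  }
}

.mod_drawing <- function(input, output, cfg, ctx) {
  writeLines(drawPipeline(ctx$spec), file.path(output, "pipeline.svg"))
}

local({
  ver <- function() as.character(utils::packageVersion("p2dock"))
  own <- function(tool) c(tool = tool, ref = "p2dock")
  .register_module("copy", .mod_passthrough, "p2dock file copy")
  .register_module("intersect", .mod_intersect, "p2dock list intersection")
  .register_module("exclude", .mod_exclude, "p2dock list exclusion")
  .register_module("human_prot_atlas", .mod_hpa,
                   "p2dock tissue-expression filter")
  .register_module("consensus", .mod_consensus,
                   "p2dock consensus restraint vote")
  .register_module("cport_like", .mod_cport_like,
                   "p2dock consensus active/passive restraints")
  .register_module("pisa_xml_extract", .mod_pisa_extract,
                   "p2dock interface XML extractor (xml2)")
  .register_module("pisa_ccp4_extract", .mod_pisa_extract,
                   "p2dock interface XML extractor (xml2)")
  .register_module("pisa_server_extract", .mod_pisa_extract,
                   "p2dock interface XML extractor (xml2)")
  .register_module("tabulate", .mod_tabulate, "p2dock IR coverage tabulator")
  .register_module("get_pattern", .mod_get_pattern,
                   "p2dock contiguous-region finder")
  .register_module("highlight_regions", .mod_highlight,
                   "p2dock viewer annotation writer")
  .register_module("pipeline_drawing", .mod_drawing,
                   "p2dock SVG pipeline diagram")
  for (stub in c("evoppi_querier", "geneid2uniprotkb", "getalphafoldpdb",
                 "getditasserpdb", "getPDB", "tm-align-cutoff",
                 "tm-align-pdb", "haddock"))
    .register_module(stub, .mod_passthrough,
                     "file-ingestion stub (pre-downloaded inputs)",
                     stub = TRUE)
})
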