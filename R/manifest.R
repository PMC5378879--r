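#' Write a run manifest for provenance
#'
#' Records the command, a hash of its configuration (stable under key
#' reordering), the RNG seed, input paths, package version and timestamps, so
#' any output directory is reproducible byte-for-byte from its manifest.
#'
#' @param dir Output directory.
#' @param command Subcommand name.
#' @param config Named list of run parameters.
#' @param rng_seed Integer seed used for the run.
#' @param input_paths Character vector of input files.
#' @param started POSIXct start time.
#' @return The manifest list, invisibly; written to `dir/manifest.json`.
#' @export
write_run_manifest <- function(dir, command, config, rng_seed,
                               input_paths = character(),
                               started = Sys.time()) {
  config <- config[order(names(config))]
  manifest <- list(
    command = command,
    config = config,
    config_hash = rlang::hash(config),
    rng_seed = as.integer(rng_seed),
    input_paths = as.character(input_paths),
    tool_version = as.character(utils::packageVersion("ncasurv")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write search results as JSON lines
#'
#' One JSON object per final module: genes (growth order), seed, per-dataset
#' NLLRT, composite score, and the growth history.
#'
#' @param result An `nca_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modules_jsonl <- function(result, path) {
  lines <- vapply(result$modules, function(m) {
    jsonlite::toJSON(list(
      genes = m$genes, seed = m$seed,
      per_dataset_nllrt = as.list(m$score$per_dataset),
      composite = m$score$composite,
      history = m$history
    ), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
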