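# Reproducibility plumbing shared by the command-line entry point
# (inst/cli/scattergap.R) and scripted runs: component-scoped child seeds,
# run manifests, and YAML run configs with CLI overrides.

#' Derive a component-scoped child seed
#'
#' Every random stage consumes a seed derived from the global seed and a
#' stable component label, so adding a stage never perturbs another stage's
#' randomness.
#'
#' @param global_seed integer global seed.
#' @param label stable component label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(global_seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(global_seed) * 69069 + h * 1013 + 1) %% 2147483647)
}

#' Write a run manifest
#'
#' Records the configuration, global seed, package version and input file
#' digests next to every artifact, so a stage can be re-run from its
#' manifest alone.
#'
#' @param path manifest file path (`.json`).
#' @param config named list of configuration values.
#' @param seed global seed of the run.
#' @param inputs character vector of input file paths to digest (size +
#'   modification-free content sum).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing manifests requires the jsonlite package")
  digest1 <- function(f) {
    b <- readBin(f, "raw", file.info(f)$size)
    sprintf("size=%d;sum=%.0f", length(b), sum(as.integer(b)))
  }
  man <- list(package = "scattergap",
              version = as.character(utils::packageVersion("scattergap")),
              seed = seed, config = config,
              inputs = if (length(inputs))
                stats::setNames(lapply(inputs, digest1), inputs)
              else NULL,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a YAML run configuration with overrides
#'
#' @param path YAML file path, or `NULL` for an empty base.
#' @param overrides named list taking precedence over file values.
#' @return Named list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading config files requires the yaml package")
    yaml::read_yaml(path)
  } else list()
  utils::modifyList(cfg, overrides)
}
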