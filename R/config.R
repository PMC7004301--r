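# Run configuration: YAML files of key: value pairs, merged with
# command-line overrides. Every run records its fully resolved
# configuration (and seed) alongside its outputs.

#' Read a run configuration file
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) lr_stop("config must be a YAML mapping")
  cfg
}

#' Merge configuration layers
#'
#' Later layers override earlier ones; `NULL` entries are ignored.
#'
#' @param ... named lists (defaults first, overrides last).
#' @return merged named list.
#' @export
merge_config <- function(...) {
  layers <- list(...)
  out <- list()
  for (l in layers) {
    if (is.null(l)) next
    for (nm in names(l)) if (!is.null(l[[nm]])) out[[nm]] <- l[[nm]]
  }
  out
}

#' Write the resolved configuration of a run
#'
#' @param config named list (should include the seed).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
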