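#' Simulation configuration objects
#'
#' A `sim_config` bundles the module name, all stage parameters, and the
#' mandatory RNG seed, and round-trips losslessly through YAML or JSON so
#' that every run can be reproduced from its serialized manifest.
#'
#' @param module Module name (e.g. `"vertex_model"`, `"tube_collapse"`,
#'   `"shear_stress"`, `"morphometrics"`, `"synthetic_data"`).
#' @param params Named list of parameters.
#' @param seed Integer RNG seed (mandatory).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(module, params = list(), seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  stopifnot(is.character(module), length(module) == 1)
  structure(list(module = module, params = params, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config [%s], seed %d, %d parameter(s)\n",
              x$module, x$seed, length(x$params)))
  invisible(x)
}

#' Read / write simulation configs (YAML or JSON by extension)
#'
#' @param config A [sim_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_config` invisibly returns `path`; `read_config` returns
#'   the [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  obj <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else stop("unsupported config extension (use .yaml/.yml/.json)")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension (use .yaml/.yml/.json)")
  sim_config(obj$module, obj$params, obj$seed)
}

#' Run manifest for an output directory
#'
#' Writes a JSON manifest with the config, seed and package version next to
#' the results of a run.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(config, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(module = config$module, params = config$params, seed = config$seed,
         package = "epitube",
         version = as.character(utils::packageVersion("epitube"))),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
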