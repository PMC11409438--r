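#' Read and write run configuration YAML
#'
#' A run configuration bundles the detection gates, screen thresholds,
#' simulation defaults, seed, output directory and log level, and round-trips
#' losslessly through YAML so every run can be reproduced from its config
#' file. Every threshold is echoed into the run-metadata JSON that
#' accompanies each output.
#'
#' @param path YAML file path.
#' @return list of class `run_config` with elements `detection`
#'   ([detection_config()]), `screen` ([screen_config()]), `simulation`
#'   ([well_sim_params()]), `seed`, `out_dir`, `log_level`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_ws("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  run_config_from_list(raw)
}

#' @rdname read_run_config
#' @param x a `run_config` (for writing) or plain list (for coercion).
#' @export
write_run_config <- function(x, path) {
  yaml::write_yaml(run_config_to_list(x), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
run_config_from_list <- function(x) {
  det <- do.call(detection_config, x$detection %||% list())
  scr <- do.call(screen_config, x$screen %||% list())
  sim_args <- x$simulation %||% list()
  if (!is.null(sim_args$geometry))
    sim_args$geometry <- do.call(worm_geometry, sim_args$geometry)
  sim <- do.call(well_sim_params, sim_args)
  cfg <- list(detection = det, screen = scr, simulation = sim,
              seed = as.integer(x$seed %||% 1L),
              out_dir = x$out_dir %||% ".",
              log_level = x$log_level %||% "quiet")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @export
run_config_to_list <- function(x) {
  sim <- unclass(x$simulation)
  sim$geometry <- unclass(sim$geometry)
  list(detection = unclass(x$detection), screen = unclass(x$screen),
       simulation = sim, seed = x$seed, out_dir = x$out_dir,
       log_level = x$log_level)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (seed ", x$seed, ", out_dir '", x$out_dir, "')\n",
      sep = "")
  print(x$detection); print(x$screen)
  invisible(x)
}

# stable content hash of a config (for run metadata)
config_hash <- function(cfg) {
  s <- yaml::as.yaml(if (inherits(cfg, "run_config"))
    run_config_to_list(cfg) else cfg)
  sprintf("%08x", hash_string(s))
}

#' Write run-metadata JSON next to an output
#'
#' Records the package version, subcommand, seed, config hash and every
#' decision threshold so that any output file can be traced to the exact
#' parameters that produced it. Content is fully determined by the inputs
#' (no timestamps), keeping reruns byte-identical.
#'
#' @param path metadata file path (conventionally `<output>.meta.json`).
#' @param subcommand the pipeline stage name.
#' @param cfg a `run_config` (or any config list).
#' @param seed the seed in effect.
#' @param extra optional named list of stage-specific settings.
#' @export
write_run_metadata <- function(path, subcommand, cfg, seed, extra = list()) {
  thresholds <- list()
  if (inherits(cfg, "run_config")) {
    thresholds <- c(unclass(cfg$screen),
                    list(detection = unclass(cfg$detection)))
  } else thresholds <- cfg
  meta <- c(list(tool = "wormscreen",
                 version = as.character(packageVersion("wormscreen")),
                 subcommand = subcommand, seed = seed,
                 config_hash = config_hash(cfg),
                 thresholds = thresholds),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
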