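# Plain-text serialization: YAML configuration, JSON node-element network
# format, CSV geometry exports, and a run manifest with content digests.

config_field_names <- function() {
  list(generation = setdiff(names(formals(generation_config)), ""),
       solver = setdiff(names(formals(solver_settings)), "verbose"),
       ensemble = c("n_samples", "master_seed", "sweep_variable",
                    "sweep_values"))
}

#' Read a validated configuration file
#'
#' The file is YAML with up to three blocks: `generation` (fields of
#' [generation_config()]), `solver` (fields of [solver_settings()]) and
#' `ensemble` (`n_samples`, `master_seed`, `sweep_variable`,
#' `sweep_values`).  Missing fields take their defaults; unknown keys are
#' rejected with the offending key path.
#'
#' @param path Path to a YAML file.  An empty file yields all defaults.
#' @return List with elements `generation`, `solver` and (if present)
#'   `ensemble`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- config_field_names()
  bad <- setdiff(names(raw), names(allowed))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (block in names(raw)) {
    unknown <- setdiff(names(raw[[block]]), allowed[[block]])
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(paste0(block, "$", unknown), collapse = ", "),
           call. = FALSE)
  }
  gen <- do.call(generation_config, raw$generation %||% list())
  sol <- do.call(solver_settings, raw$solver %||% list())
  out <- list(generation = gen, solver = sol)
  if (!is.null(raw$ensemble)) {
    e <- raw$ensemble
    out$ensemble <- ensemble_spec(gen,
                                  n_samples = e$n_samples %||% 2L,
                                  master_seed = e$master_seed %||% 1L,
                                  sweep_variable = e$sweep_variable,
                                  sweep_values = unlist(e$sweep_values))
  }
  out
}

#' Write a configuration file
#'
#' @param config List as returned by [read_config()], or a bare
#'   [generation_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "generation_config"))
    config <- list(generation = config)
  out <- list()
  if (!is.null(config$generation))
    out$generation <- Filter(Negate(is.null), unclass(config$generation))
  if (!is.null(config$solver)) {
    s <- unclass(config$solver)
    s$verbose <- NULL
    out$solver <- s
  }
  if (!is.null(config$ensemble)) {
    e <- config$ensemble
    out$ensemble <- Filter(Negate(is.null),
                           list(n_samples = e$n_samples,
                                master_seed = e$master_seed,
                                sweep_variable = e$sweep_variable,
                                sweep_values = e$sweep_values))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Serialize a network to the JSON node-element format
#'
#' Writes node, beam and cable tables plus the generating configuration,
#' material parameters and achieved density; [read_network()] restores an
#' equivalent `filament_network`.  Serialization is deterministic for a
#' fixed network.
#'
#' @param network A `filament_network`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "filament_network"))
  mat <- network$materials
  obj <- list(
    format = "actinform-network",
    version = 1L,
    config = Filter(Negate(is.null), unclass(network$config)),
    materials = list(
      filament_modulus = mat$filament_modulus,
      filament_diameter = mat$filament_diameter,
      filament_yield_force = mat$filament_yield_force,
      crosslinker_yield_force = mat$crosslinker_yield_force,
      crosslinker_prestress = mat$crosslinker_prestress,
      crosslinker_axial_stiffness = mat$crosslinker_axial_stiffness),
    achieved_relative_density = network$achieved_relative_density,
    seed = network$seed,
    filaments = as.data.frame(network$filaments),
    nodes = as.data.frame(network$nodes),
    beams = as.data.frame(network$beams),
    cables = as.data.frame(network$cables)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Path to the JSON file.
#' @return A `filament_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "actinform-network"))
    stop("not an actinform network file: ", path, call. = FALSE)
  cfg_args <- obj$config
  cfg <- do.call(generation_config, cfg_args)
  mat <- do.call(material_table, obj$materials)
  nodes <- tibble::as_tibble(obj$nodes)
  beams <- tibble::as_tibble(obj$beams)
  cables <- tibble::as_tibble(obj$cables)
  comp <- network_components(NROW(nodes), beams, cables)
  structure(list(
    filaments = tibble::as_tibble(obj$filaments),
    nodes = nodes, beams = beams, cables = cables,
    materials = mat, config = cfg,
    achieved_relative_density = obj$achieved_relative_density,
    component = comp$membership,
    n_components = comp$no,
    seed = obj$seed
  ), class = "filament_network")
}

#' Export plot-ready geometry tables
#'
#' Writes `nodes.csv`, `beams.csv`, `cables.csv` and a line-segment table
#' `segments.csv` (`x1, y1, x2, y2, kind` with kind `beam` or `cable`) for
#' a network, optionally at a deformed state.  An empty network produces
#' headers-only files.
#'
#' @param network A `filament_network`.
#' @param dir Output directory (created if missing).
#' @param state Optional `system_state` supplying deformed coordinates.
#' @return The directory, invisibly.
#' @export
export_geometry <- function(network, dir, state = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- as.data.frame(network$nodes)
  if (!is.null(state)) {
    nodes$x <- state$coordinates[, 1]
    nodes$y <- state$coordinates[, 2]
  }
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(network$beams),
                   file.path(dir, "beams.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(network$cables),
                   file.path(dir, "cables.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(segment_table(network, state)),
                   file.path(dir, "segments.csv"), row.names = FALSE)
  invisible(dir)
}

#' Build a run manifest with content digests
#'
#' Lists every output file of a pipeline run with its MD5 content digest,
#' alongside the configuration snapshot, package version, master seed and
#' per-stage wall-clock times, so that the run can be reproduced from the
#' manifest alone.
#'
#' @param out_dir Directory whose files are listed.
#' @param config Configuration list (as from [read_config()]).
#' @param master_seed Integer master seed of the run.
#' @param stage_times Named numeric vector of per-stage seconds (optional).
#' @param path Where to write the manifest JSON (default
#'   `out_dir/manifest.json`).
#' @return The manifest list, invisibly.
#' @export
run_manifest <- function(out_dir, config = NULL, master_seed = NULL,
                         stage_times = NULL,
                         path = file.path(out_dir, "manifest.json")) {
  files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                   normalizePath(path, mustWork = FALSE))
  digests <- tools::md5sum(files)
  manifest <- list(
    package = "actinform",
    version = as.character(utils::packageVersion("actinform")),
    master_seed = master_seed,
    config = if (!is.null(config)) rapply(config, unclass, how = "replace"),
    stage_times_sec = as.list(stage_times),
    files = data.frame(file = basename(names(digests)),
                       md5 = unname(digests), row.names = NULL)
  )
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}
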