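#' Default run configuration
#'
#' All tunables of the pipeline with their documented defaults. The
#' configuration is a flat named list carrying a versioned schema key;
#' \code{\link{load_config}} validates files against it.
#'
#' @return Named list of tunables:
#' \describe{
#'   \item{schema_version}{Config schema version (1).}
#'   \item{seed}{Default RNG seed for generators (1).}
#'   \item{noise_sd_rel}{Relative multiplicative noise SD (0.01).}
#'   \item{contact_cutoff}{Protein--micelle contact cutoff, Angstrom (6.5).}
#'   \item{salt_bridge_cutoff}{Charged heavy-atom distance defining a salt
#'     bridge, Angstrom (4.0).}
#'   \item{persistence}{Occupancy fraction above which a salt bridge counts
#'     as stable (0.5).}
#'   \item{N_agg}{Micelle aggregation number (17).}
#'   \item{CMC}{Critical micellar concentration, M (4.5e-6).}
#'   \item{probe_radius}{SASA probe radius, Angstrom (1.4).}
#'   \item{n_sphere_points}{Shrake-Rupley sphere points per atom (960).}
#'   \item{rdf_bin_width}{RDF bin width, Angstrom (0.5).}
#'   \item{rayleigh_halfwidth}{Half-width of the Rayleigh diagonal mask in
#'     excitation-emission matrices, nm (10).}
#'   \item{path_cm}{CD cell path length, cm (0.1).}
#' }
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    noise_sd_rel = 0.01,
    contact_cutoff = 6.5,
    salt_bridge_cutoff = 4.0,
    persistence = 0.5,
    N_agg = 17L,
    CMC = 4.5e-6,
    probe_radius = 1.4,
    n_sphere_points = 960L,
    rdf_bin_width = 0.5,
    rayleigh_halfwidth = 10,
    path_cm = 0.1
  )
}

#' Load a JSON run configuration
#'
#' Reads a JSON file of tunables and merges it over
#' \code{\link{default_config}}. Unknown keys are hard errors (typo guard);
#' values must match the type of the default they replace. An empty file or
#' empty JSON object yields the full default configuration.
#'
#' @param path Path to a JSON file.
#' @return Validated configuration list (class \code{"run_config"}).
#' @export
load_config <- function(path) {
  defaults <- default_config()
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user)) stop("config error: top level must be a JSON object",
                           call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defaults
  for (k in names(user)) {
    v <- user[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config error: key '", k, "' must be a single finite number",
           call. = FALSE)
    cfg[[k]] <- if (is.integer(defaults[[k]])) {
      if (v != round(v))
        stop("config error: key '", k, "' must be an integer", call. = FALSE)
      as.integer(v)
    } else as.numeric(v)
  }
  if (cfg$schema_version != 1L)
    stop("config error: unsupported schema_version ", cfg$schema_version,
         call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration to JSON
#'
#' @param cfg Configuration list as returned by \code{\link{default_config}}
#'   or \code{\link{load_config}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(is.list(cfg))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
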