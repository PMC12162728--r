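#' Scaffold design configuration
#'
#' Collects every parameter of the generation pipeline.  Defaults reproduce
#' the reference configuration: a cube of 500 units of length (1 unit = 1
#' voxel = 15 um at full scale), 300 seeds with a hard-core minimum mutual
#' distance of 25 units, 5000 target edges of which 70% are selected
#' deterministically by angular distance from the target orientation.
#'
#' @param domain_edge_length edge of the cubic design domain, units of length
#' @param n_seeds number of Voronoi seeds
#' @param min_seed_distance hard-core minimum distance between seeds
#' @param n_edges_target number of edges kept by the selection step
#' @param beta_z target trabecular orientation in degrees from the z axis,
#'   in `[0, 90]`, or `"isotropic"` for the bin-balanced selection
#' @param deterministic_fraction fraction of `n_edges_target` selected
#'   deterministically by smallest angular distance (the rest is drawn by
#'   the probabilistic accept/reject loop)
#' @param voxel_pitch physical voxel size in micrometres at full scale
#' @param rng_seed integer seed driving every random draw of the pipeline
#' @return an object of class `design_config`
#' @examples
#' cfg <- design_config(beta_z = 0, rng_seed = 1)
#' cfg$seed_density  # 2.4e-6 for the reference configuration
#' @export
design_config <- function(domain_edge_length = 500, n_seeds = 300,
                          min_seed_distance = 25, n_edges_target = 5000,
                          beta_z = "isotropic", deterministic_fraction = 0.7,
                          voxel_pitch = 15, rng_seed = 1L) {
  stop_if_not_scalar(domain_edge_length, "domain_edge_length")
  stop_if_not_scalar(n_seeds, "n_seeds")
  stop_if_not_scalar(min_seed_distance, "min_seed_distance")
  stop_if_not_scalar(n_edges_target, "n_edges_target")
  stop_if_not_scalar(deterministic_fraction, "deterministic_fraction")
  stop_if_not_scalar(voxel_pitch, "voxel_pitch")
  if (min_seed_distance <= 0) stop("min_seed_distance must be > 0")
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  if (deterministic_fraction < 0 || deterministic_fraction > 1)
    stop("deterministic_fraction must be in [0, 1]")
  isotropic <- identical(beta_z, "isotropic") || isTRUE(is.na(beta_z))
  if (!isotropic) {
    stop_if_not_scalar(beta_z, "beta_z")
    if (beta_z < 0 || beta_z > 90) stop("beta_z must be in [0, 90] degrees")
  }
  cfg <- structure(list(
    domain_edge_length = domain_edge_length,
    n_seeds = as.integer(n_seeds),
    min_seed_distance = min_seed_distance,
    n_edges_target = as.integer(n_edges_target),
    beta_z = if (isotropic) "isotropic" else beta_z,
    deterministic_fraction = deterministic_fraction,
    voxel_pitch = voxel_pitch,
    rng_seed = as.integer(rng_seed),
    seed_density = n_seeds / domain_edge_length^3
  ), class = "design_config")
  cfg
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  domain: %g^3, seeds: %d (dmin %g), density %.3g\n",
              x$domain_edge_length, x$n_seeds, x$min_seed_distance,
              x$seed_density))
  cat(sprintf("  target edges: %d, beta_z: %s, deterministic fraction: %g\n",
              x$n_edges_target, format(x$beta_z), x$deterministic_fraction))
  cat(sprintf("  voxel pitch: %g um, rng seed: %d\n", x$voxel_pitch,
              x$rng_seed))
  invisible(x)
}

#' Read a design configuration from JSON or YAML
#'
#' Unknown fields raise an error, missing fields fall back to the defaults
#' of [design_config()].
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`)
#' @return a `design_config`
#' @export
read_design_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configurations")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(design_config))
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "))
  do.call(design_config, lst)
}

#' Write a design configuration
#'
#' @param config a `design_config`
#' @param path output path (`.json` or `.yaml`)
#' @export
write_design_config <- function(config, path) {
  lst <- unclass(config)
  lst$seed_density <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML configurations")
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
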