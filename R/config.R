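#' Read and validate a run configuration
#'
#' The configuration is YAML with blocks mirroring the pipeline stages:
#' `detector`, `collimator`, `geometry`, `phantom`, `simulation`,
#' `reconstruction`, `analysis`. Unknown keys are rejected. All lengths are
#' mm, times s, concentrations MBq/mL.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated config list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("I/O error: no such config file: ", path)
    yaml::read_yaml(path)
  }
  allowed <- list(
    detector = c("width", "height", "pixel_pitch", "intrinsic_fwhm",
                 "crystal_thickness"),
    collimator = c("diameter", "material", "mu", "acceptance_full_angle"),
    geometry = c("dist_pinhole_target", "dist_pinhole_detector",
                 "n_projections", "angles"),
    phantom = c("type", "sector_diameters", "cylinder_diameter",
                "cylinder_height", "inner_diameter", "edge_gap", "length",
                "concentration", "positions", "activities",
                "fov", "voxel_size"),
    simulation = c("exposure", "calibration", "counts_per_frame", "seed",
                   "aperture_samples"),
    reconstruction = c("n_iterations", "n_subsets", "smooth_width",
                       "smooth_every", "epsilon", "track_likelihood"),
    analysis = c("criterion", "axial_fraction"))
  extra_top <- setdiff(names(cfg), names(allowed))
  if (length(extra_top) > 0)
    stop("config error: unknown block(s): ", paste(extra_top, collapse = ", "))
  for (blk in names(cfg)) {
    extra <- setdiff(names(cfg[[blk]]), allowed[[blk]])
    if (length(extra) > 0)
      stop("config error: unknown key(s) in ", blk, ": ",
           paste(extra, collapse = ", "))
  }
  for (blk in c("detector", "collimator", "geometry", "phantom"))
    if (is.null(cfg[[blk]]))
      stop("config error: missing required block: ", blk)
  structure(cfg, class = c("run_config", "list"))
}

#' Build the system model described by a config
#'
#' @param cfg A `run_config` (or list in config shape).
#' @return A [system_model()].
#' @export
config_model <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- read_config(cfg)
  det <- do.call(detector_spec, cfg$detector)
  col <- do.call(collimator_spec, cfg$collimator)
  geo <- do.call(acquisition_geometry, cfg$geometry)
  nap <- cfg$simulation$aperture_samples
  system_model(det, col, geo, aperture_samples = if (is.null(nap)) 7 else nap)
}

#' Build the phantom described by a config
#'
#' @param cfg A `run_config`.
#' @return A [volume_image()] with ground-truth descriptor attribute (except
#'   for point-source phantoms).
#' @export
config_phantom <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- read_config(cfg)
  ph <- cfg$phantom
  grid <- volume_template(unlist(ph$fov), unlist(ph$voxel_size))
  keep <- function(x, keys) x[intersect(names(x), keys)]
  switch(ph$type,
    jaszczak = make_jaszczak(do.call(jaszczak_spec,
      keep(ph, c("sector_diameters", "cylinder_diameter", "cylinder_height",
                 "concentration"))), grid),
    capillary = make_capillary(do.call(capillary_spec,
      keep(ph, c("inner_diameter", "edge_gap", "length", "concentration"))),
      grid),
    points = make_point_sources(
      do.call(rbind, lapply(ph$positions, unlist)),
      unlist(ph$activities), grid),
    stop("config error: unknown phantom type: ", ph$type))
}

config_recon_settings <- function(cfg) {
  rc <- cfg$reconstruction
  if (is.null(rc)) rc <- list()
  do.call(recon_settings, rc)
}

# Polynomial rolling hash (base 31, modulus 2^31 - 1, exact in doubles) of
# a character string; stamps artifacts with the configuration they came
# from. Cache invalidation only -- not cryptographic.
text_hash <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  text_hash(paste(utils::capture.output(utils::str(unclass(cfg),
                                                   digits.d = 12)),
                  collapse = "\n"))
}
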