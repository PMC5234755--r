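.pinspect_cache <- new.env(parent = emptyenv())

#' Projection set
#'
#' An ordered stack of 2-D detector frames, one per rotation angle, plus the
#' acquisition metadata and a fingerprint of the system model that produced
#' (or is assumed to have produced) them.
#'
#' @param frames Numeric array `[n_u, n_v, n_frames]`, all values >= 0.
#' @param pixel_pitch Detector pixel size, mm.
#' @param angles Rotation angle per frame, degrees.
#' @param exposure Exposure per frame, s.
#' @param fingerprint System-model fingerprint string.
#' @param counts `"expected"` (real-valued means) or `"observed"`
#'   (integer Poisson counts).
#' @param calibration Count calibration constant used by the simulation.
#' @param seed Seed used for noise generation, if any.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(frames, pixel_pitch, angles, exposure,
                           fingerprint = "", counts = "expected",
                           calibration = 1, seed = NA_integer_) {
  if (length(dim(frames)) != 3) stop("frames must be a 3-D array [nu, nv, n]")
  if (dim(frames)[3] != length(angles))
    stop("consistency error: frame count must equal angle count")
  if (any(frames < 0)) stop("projection values must be non-negative")
  structure(list(frames = frames, pixel_pitch = pixel_pitch,
                 angles = as.numeric(angles), exposure = exposure,
                 fingerprint = fingerprint, counts = counts,
                 calibration = calibration, seed = seed),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("projection_set: %d frames of %d x %d px @ %.3g mm, %s counts, mean %.4g counts/frame\n",
              d[3], d[1], d[2], x$pixel_pitch, x$counts,
              mean(apply(x$frames, 3, sum))))
  invisible(x)
}

# Detector intrinsic blur: symmetric zero-boundary Gaussian convolution in
# the detector plane. Symmetric Toeplitz matrices, hence self-adjoint --
# applying the same blur in forward and adjoint keeps the operator pair an
# exact transpose.
detector_blur_matrices <- function(model) {
  sigma_px <- model$detector$intrinsic_fwhm / (2 * sqrt(2 * log(2))) /
    model$detector$pixel_pitch
  list(u = conv_matrix(model$detector$n_u, sigma_px, boundary = "zero"),
       v = conv_matrix(model$detector$n_v, sigma_px, boundary = "zero"))
}

blur_frames <- function(frames, bl) {
  for (a in seq_len(dim(frames)[3]))
    frames[, , a] <- bl$u %*% frames[, , a] %*% bl$v
  frames
}

forward_raw <- function(values, voxel, origin, model, subset, scale) {
  g <- model$geometry
  angles <- g$angles[subset]
  fr <- splat_forward_cpp(as.numeric(values), as.integer(dim(values)),
                          as.numeric(voxel), as.numeric(origin),
                          angles * pi / 180,
                          g$dist_pinhole_target, g$dist_pinhole_detector,
                          aperture_sample_points(model),
                          model$detector$n_u, model$detector$n_v,
                          model$detector$pixel_pitch, scale)
  dim(fr) <- c(model$detector$n_u, model$detector$n_v, length(angles))
  blur_frames(fr, detector_blur_matrices(model))
}

adjoint_raw <- function(frames, voldim, voxel, origin, model, subset, scale) {
  g <- model$geometry
  angles <- g$angles[subset]
  fr <- blur_frames(frames, detector_blur_matrices(model))
  v <- splat_adjoint_cpp(as.numeric(fr), as.integer(voldim),
                         as.numeric(voxel), as.numeric(origin),
                         angles * pi / 180,
                         g$dist_pinhole_target, g$dist_pinhole_detector,
                         aperture_sample_points(model),
                         model$detector$n_u, model$detector$n_v,
                         model$detector$pixel_pitch, scale)
  array(v, voldim)
}

proj_scale <- function(model, exposure, calibration) {
  calibration * exposure / model$aperture_samples
}

#' Forward-project a volume
#'
#' Maps an activity volume to the stack of expected detector count images:
#' for each angle the volume is rotated about the z axis, every voxel is
#' mapped through each sample point of the effective aperture disc onto the
#' detector with a solid-angle weight, and the resulting frame is convolved
#' with the detector intrinsic Gaussian. The operator is linear in the
#' volume and exactly matched with [back_project()].
#'
#' @param volume A [volume_image()]; its transverse extent must fit within
#'   [max_target_diameter()].
#' @param model A [system_model()].
#' @param exposure Exposure per frame, s (default 60).
#' @param calibration Counts per (MBq/mL x mm^3 x s) proxy constant scaling
#'   expected counts (default 1).
#' @param subset Optional integer indices restricting the angles.
#' @return A [projection_set()] of expected counts.
#' @export
forward_project <- function(volume, model, exposure = 60, calibration = 1,
                            subset = NULL) {
  stopifnot(inherits(volume, "volume_image"), inherits(model, "system_model"))
  nz <- which(volume$values > 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    xs <- volume$origin[1] + (nz[, 1] - 0.5) * volume$voxel_size[1]
    ys <- volume$origin[2] + (nz[, 2] - 0.5) * volume$voxel_size[2]
    if (2 * sqrt(max(xs^2 + ys^2)) > max_target_diameter(model) + 1e-9)
      stop("target-too-large: rotating activity support exceeds the field of view")
  }
  if (is.null(subset)) subset <- seq_along(model$geometry$angles)
  scale <- proj_scale(model, exposure, calibration) * prod(volume$voxel_size)
  fr <- forward_raw(volume$values, volume$voxel_size, volume$origin,
                    model, subset, scale)
  projection_set(fr, model$detector$pixel_pitch,
                 model$geometry$angles[subset], exposure,
                 fingerprint = model_fingerprint(model),
                 counts = "expected", calibration = calibration)
}

#' Back-project a projection set
#'
#' Exact adjoint of [forward_project()]: the frames are convolved with the
#' (self-adjoint) detector blur and gathered along the same rays with the
#' same weights, transposed.
#'
#' @param projections A [projection_set()] whose fingerprint matches `model`.
#' @param model A [system_model()].
#' @param grid A [volume_image()] template defining the output voxel grid.
#' @param subset Optional integer indices (into `model$geometry$angles`)
#'   identifying which angles the frames correspond to.
#' @return A [volume_image()].
#' @export
back_project <- function(projections, model, grid, subset = NULL) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(model, "system_model"), inherits(grid, "volume_image"))
  if (nzchar(projections$fingerprint) &&
      !identical(projections$fingerprint, model_fingerprint(model)))
    stop("geometry error: projection set fingerprint does not match the model")
  if (is.null(subset)) subset <- seq_along(model$geometry$angles)
  if (length(subset) != dim(projections$frames)[3])
    stop("consistency error: subset length must equal frame count")
  scale <- proj_scale(model, projections$exposure, projections$calibration) *
    prod(grid$voxel_size)
  v <- adjoint_raw(projections$frames, dim(grid$values), grid$voxel_size,
                   grid$origin, model, subset, scale)
  v[v < 0] <- 0
  volume_image(v, grid$voxel_size, grid$origin)
}

#' Sensitivity map
#'
#' Back-projection of an all-ones projection set: the voxel-wise normalizer
#' of the MLEM update. Cached per (model, grid, exposure, calibration,
#' subset).
#'
#' @inheritParams back_project
#' @param exposure Exposure per frame, s.
#' @param calibration Calibration constant.
#' @return A [volume_image()] strictly positive inside the field of view.
#' @export
sensitivity_map <- function(model, grid, exposure = 60, calibration = 1,
                            subset = NULL) {
  stopifnot(inherits(model, "system_model"), inherits(grid, "volume_image"))
  if (is.null(subset)) subset <- seq_along(model$geometry$angles)
  key <- paste(model_fingerprint(model), model$aperture_samples,
               paste(dim(grid$values), collapse = "x"),
               paste(signif(grid$voxel_size, 10), collapse = ","),
               paste(signif(grid$origin, 10), collapse = ","),
               signif(exposure, 10), signif(calibration, 10),
               paste(subset, collapse = ","), sep = "#")
  hit <- .pinspect_cache[[key]]
  if (!is.null(hit)) return(hit)
  ones <- projection_set(
    array(1, c(model$detector$n_u, model$detector$n_v, length(subset))),
    model$detector$pixel_pitch, model$geometry$angles[subset],
    exposure, fingerprint = model_fingerprint(model),
    calibration = calibration)
  s <- back_project(ones, model, grid, subset = subset)
  .pinspect_cache[[key]] <- s
  s
}

#' Poisson count simulation
#'
#' Replaces each expected-count pixel by an independent Poisson draw with
#' that mean. Reproducible: the R RNG state is set from `seed` locally and
#' restored afterwards.
#'
#' @param projections A [projection_set()] of expected counts (>= 0).
#' @param seed Integer seed.
#' @return A [projection_set()] of integer observed counts.
#' @export
add_poisson_noise <- function(projections, seed) {
  stopifnot(inherits(projections, "projection_set"))
  if (any(projections$frames < 0))
    stop("invalid-mean: expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fr <- projections$frames
  fr[] <- stats::rpois(length(fr), lambda = as.numeric(fr))
  projection_set(fr, projections$pixel_pitch, projections$angles,
                 projections$exposure, projections$fingerprint,
                 counts = "observed", calibration = projections$calibration,
                 seed = as.integer(seed))
}

#' Scale expected projections to a target count level
#'
#' Multiplies the expected counts (and the recorded calibration constant) so
#' that the mean total counts per frame equals `counts_per_frame`. Used to
#' set the acquisition count level when the absolute camera efficiency is
#' not modelled.
#'
#' @param projections A [projection_set()] of expected counts.
#' @param counts_per_frame Desired mean total counts per frame.
#' @return A rescaled [projection_set()].
#' @export
calibrate_counts <- function(projections, counts_per_frame) {
  stopifnot(inherits(projections, "projection_set"), counts_per_frame > 0)
  cur <- mean(apply(projections$frames, 3, sum))
  if (cur <= 0) stop("cannot calibrate an all-zero projection set")
  fac <- counts_per_frame / cur
  projection_set(projections$frames * fac, projections$pixel_pitch,
                 projections$angles, projections$exposure,
                 projections$fingerprint, counts = projections$counts,
                 calibration = projections$calibration * fac)
}
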