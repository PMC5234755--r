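#' Detector specification
#'
#' Describes the gamma-camera detector as seen by the projector: a planar
#' useful area discretized into square pixels, plus the intrinsic spatial
#' resolution of the crystal/PMT chain expressed as a Gaussian FWHM in the
#' detector plane.
#'
#' @param width Useful detector width in mm (default 540, a large-field
#'   clinical camera).
#' @param height Useful detector height in mm (default 400).
#' @param pixel_pitch Pixel size in mm of the recorded matrix.
#' @param intrinsic_fwhm Intrinsic spatial resolution (FWHM, mm) measured at
#'   the detector face (default 3.9).
#' @param crystal_thickness Crystal thickness in mm; metadata only, not used
#'   by the projector (default 9.5).
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(width = 540, height = 400, pixel_pitch = 2,
                          intrinsic_fwhm = 3.9, crystal_thickness = 9.5) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(pixel_pitch),
            is.numeric(intrinsic_fwhm))
  if (width <= 0 || height <= 0 || pixel_pitch <= 0 || intrinsic_fwhm <= 0)
    stop("invalid-geometry: detector dimensions, pitch and intrinsic FWHM must be positive")
  n_u <- floor(width / pixel_pitch)
  n_v <- floor(height / pixel_pitch)
  if (n_u < 2 || n_v < 2)
    stop("invalid-geometry: detector must span at least 2 pixels per axis")
  structure(list(width = width, height = height, pixel_pitch = pixel_pitch,
                 intrinsic_fwhm = intrinsic_fwhm,
                 crystal_thickness = crystal_thickness,
                 n_u = as.integer(n_u), n_v = as.integer(n_v)),
            class = "detector_spec")
}

#' Pinhole collimator specification
#'
#' A single double-cone pinhole bored in a dense metal slab. Photon
#' penetration through the aperture edges makes the hole act larger than its
#' physical bore; the effect is controlled by the linear attenuation
#' coefficient `mu` of the material at the emission energy and by the opening
#' angle of the double cone.
#'
#' @param diameter Physical bore diameter in mm.
#' @param material `"lead"` or `"tungsten"`. Sets the default `mu` at 140 keV
#'   (2.7 and 3.6 mm^-1 respectively) when `mu` is not given.
#' @param mu Linear attenuation coefficient in mm^-1 at the emission energy.
#' @param acceptance_full_angle Full opening angle of the double cone, degrees
#'   (default 60).
#' @return An object of class `collimator_spec`.
#' @export
collimator_spec <- function(diameter, material = c("lead", "tungsten"),
                            mu = NULL, acceptance_full_angle = 60) {
  material <- match.arg(material)
  if (is.null(mu)) mu <- c(lead = 2.7, tungsten = 3.6)[[material]]
  if (!is.numeric(diameter) || diameter < 0)
    stop("invalid-geometry: pinhole diameter must be >= 0")
  if (!is.numeric(mu) || mu <= 0)
    stop("invalid-material: attenuation coefficient mu must be positive")
  if (acceptance_full_angle <= 0 || acceptance_full_angle >= 180)
    stop("invalid-geometry: acceptance full angle must lie in (0, 180) degrees")
  structure(list(diameter = diameter, material = material, mu = mu,
                 acceptance_full_angle = acceptance_full_angle),
            class = "collimator_spec")
}

#' Rotating-target acquisition geometry
#'
#' The target sits on a rotation axis (z) at distance `dist_pinhole_target`
#' (b) from the pinhole; the detector plane lies `dist_pinhole_detector` (f)
#' beyond the pinhole on the opposite side. The target is rotated to the
#' listed angles and one projection is recorded per angle.
#'
#' @param dist_pinhole_target Pinhole-to-rotation-axis distance b, mm.
#' @param dist_pinhole_detector Pinhole-to-detector distance f, mm.
#' @param n_projections Number of projections; used to generate uniform
#'   `angles` when they are not supplied.
#' @param angles Projection angles in degrees, strictly increasing, spanning
#'   less than 360. Default: `n_projections` uniform steps starting at 0.
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(dist_pinhole_target, dist_pinhole_detector,
                                 n_projections = 40, angles = NULL) {
  b <- dist_pinhole_target; f <- dist_pinhole_detector
  if (!is.numeric(b) || !is.numeric(f) || b <= 0 || f <= 0)
    stop("invalid-geometry: pinhole-target and pinhole-detector distances must be positive")
  if (is.null(angles))
    angles <- seq(0, 360, length.out = n_projections + 1)[seq_len(n_projections)]
  if (length(angles) != n_projections)
    stop("invalid-geometry: length(angles) must equal n_projections")
  if (any(diff(angles) <= 0) || (max(angles) - min(angles)) >= 360)
    stop("invalid-geometry: angles must be strictly increasing and span < 360 degrees")
  structure(list(dist_pinhole_target = b, dist_pinhole_detector = f,
                 n_projections = as.integer(n_projections),
                 angles = as.numeric(angles), rotation_axis = "z"),
            class = "acquisition_geometry")
}

#' Full system model
#'
#' Bundles detector, collimator and acquisition geometry into the forward
#' operator definition for one configuration. `aperture_samples` controls how
#' many points across the effective aperture disc are averaged by the
#' projector (1 = ideal pinhole; default 7).
#'
#' @param detector A [detector_spec()].
#' @param collimator A [collimator_spec()].
#' @param geometry An [acquisition_geometry()].
#' @param aperture_samples Number of sub-aperture sample points (>= 1).
#' @return An object of class `system_model`.
#' @export
system_model <- function(detector, collimator, geometry, aperture_samples = 7) {
  stopifnot(inherits(detector, "detector_spec"),
            inherits(collimator, "collimator_spec"),
            inherits(geometry, "acquisition_geometry"))
  if (aperture_samples < 1) stop("invalid-geometry: aperture_samples must be >= 1")
  structure(list(detector = detector, collimator = collimator,
                 geometry = geometry,
                 aperture_samples = as.integer(aperture_samples)),
            class = "system_model")
}

#' Magnification factor
#'
#' Ratio of the pinhole-to-detector distance to the pinhole-to-target
#' distance, M = f / b. Transverse structure at the rotation axis is imaged
#' at M times its size (and inverted).
#'
#' @param geometry An [acquisition_geometry()] (or a `system_model`).
#' @return Dimensionless magnification M.
#' @export
magnification <- function(geometry) {
  if (inherits(geometry, "system_model")) geometry <- geometry$geometry
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$dist_pinhole_detector / geometry$dist_pinhole_target
}

#' Effective pinhole diameter
#'
#' Physical bore enlarged for edge penetration:
#' `d_eff = sqrt(d * (d + (2/mu) * tan(alpha/2)))`, where `mu` is the linear
#' attenuation coefficient and `alpha` the full opening angle of the double
#' cone. For an opaque material (`mu -> Inf`) this reduces to the physical
#' diameter.
#'
#' @param collimator A [collimator_spec()].
#' @return Effective diameter in mm.
#' @export
effective_pinhole_diameter <- function(collimator) {
  stopifnot(inherits(collimator, "collimator_spec"))
  d <- collimator$diameter
  mu <- collimator$mu
  if (!is.numeric(mu) || mu <= 0)
    stop("invalid-material: mu must be positive")
  alpha <- collimator$acceptance_full_angle * pi / 180
  sqrt(d * (d + (2 / mu) * tan(alpha / 2)))
}

#' Predicted system spatial resolution
#'
#' FWHM at the target plane, combining the demagnified detector intrinsic
#' resolution and the geometric aperture term in quadrature:
#' `R = sqrt((R_int / M)^2 + (d_eff * (M + 1) / M)^2)`.
#'
#' @param model A [system_model()].
#' @return Predicted FWHM in mm at the target plane.
#' @export
predicted_system_resolution <- function(model) {
  stopifnot(inherits(model, "system_model"))
  M <- magnification(model$geometry)
  if (M <= 0) stop("invalid-geometry: magnification must be positive")
  r_int <- model$detector$intrinsic_fwhm
  d_eff <- effective_pinhole_diameter(model$collimator)
  sqrt((r_int / M)^2 + (d_eff * (M + 1) / M)^2)
}

#' Maximum target diameter
#'
#' Largest diameter of a cylinder centred on the rotation axis whose
#' projection stays inside the detector's useful area at every rotation
#' angle; for the central geometry this is `min(width, height) / M`.
#'
#' @param model A [system_model()].
#' @return Maximum target diameter in mm.
#' @export
max_target_diameter <- function(model) {
  stopifnot(inherits(model, "system_model"))
  M <- magnification(model$geometry)
  if (M <= 0) stop("invalid-geometry: magnification must be positive")
  min(model$detector$width, model$detector$height) / M
}

#' Ideal-pinhole central-ray projection of a point
#'
#' Rotates `point` (target frame, mm; rotation axis = z) by `angle` degrees
#' counter-clockwise about +z, then maps it through the pinhole centre onto
#' the detector plane. Transverse offsets at the rotation axis scale by -M
#' (inverted image); points nearer the pinhole magnify more.
#'
#' @param model A [system_model()].
#' @param point Numeric length-3 (x, y, z) in mm, target frame. The pinhole
#'   sits at (0, b, 0); the detector plane is y = b + f.
#' @param angle Rotation angle in degrees.
#' @return Numeric length-2 (u, v) detector coordinates in mm, measured from
#'   the detector centre (u along x, v along z).
#' @export
project_point <- function(model, point, angle = 0) {
  stopifnot(inherits(model, "system_model"), length(point) == 3)
  g <- model$geometry
  b <- g$dist_pinhole_target; f <- g$dist_pinhole_detector
  th <- angle * pi / 180
  xr <- point[1] * cos(th) - point[2] * sin(th)
  yr <- point[1] * sin(th) + point[2] * cos(th)
  zr <- point[3]
  if (yr >= b)
    stop("invalid-geometry: point must lie on the target side of the pinhole plane")
  s <- f / (b - yr)
  uv <- c(-s * xr, -s * zr)
  if (abs(uv[1]) > model$detector$width / 2 || abs(uv[2]) > model$detector$height / 2)
    stop("out-of-field: projected ray misses the detector useful area")
  uv
}

#' @export
print.system_model <- function(x, ...) {
  M <- magnification(x$geometry)
  cat("Pinhole SPECT system model\n")
  cat(sprintf("  detector: %.0f x %.0f mm, pitch %.3g mm (%d x %d px), intrinsic FWHM %.2f mm\n",
              x$detector$width, x$detector$height, x$detector$pixel_pitch,
              x$detector$n_u, x$detector$n_v, x$detector$intrinsic_fwhm))
  cat(sprintf("  collimator: %s, bore %.2f mm, mu %.2f /mm, d_eff %.3f mm\n",
              x$collimator$material, x$collimator$diameter, x$collimator$mu,
              effective_pinhole_diameter(x$collimator)))
  cat(sprintf("  geometry: b %.1f mm, f %.1f mm (M = %.2fx), %d projections\n",
              x$geometry$dist_pinhole_target, x$geometry$dist_pinhole_detector,
              M, x$geometry$n_projections))
  cat(sprintf("  predicted resolution %.3f mm FWHM; max target %.1f mm; %d aperture samples\n",
              predicted_system_resolution(x), max_target_diameter(x),
              x$aperture_samples))
  invisible(x)
}

# Canonical string identifying the acquisition (detector, collimator,
# distances, angles); stored in projection sets and checked by the
# reconstruction. A readable fingerprint, not a hash. aperture_samples is a
# numerical discretization choice of the operator, not acquisition physics,
# so it is deliberately excluded: data may be simulated with a finer
# aperture sampling than the reconstruction model uses.
model_fingerprint <- function(model) {
  stopifnot(inherits(model, "system_model"))
  d <- model$detector; c_ <- model$collimator; g <- model$geometry
  paste(sep = "|",
        sprintf("det=%dx%d@%.6g", d$n_u, d$n_v, d$pixel_pitch),
        sprintf("fwhm=%.6g", d$intrinsic_fwhm),
        sprintf("col=%s,d=%.6g,mu=%.6g,alpha=%.6g", c_$material, c_$diameter,
                c_$mu, c_$acceptance_full_angle),
        sprintf("b=%.6g,f=%.6g", g$dist_pinhole_target, g$dist_pinhole_detector),
        sprintf("ang=%s", paste(sprintf("%.4f", g$angles), collapse = ",")))
}

# Deterministic sampling of the effective aperture disc. Small n (<= 12):
# a centre point plus one ring of equally spaced points (ring only for even
# n), with the ring radius set so the mean-square radius matches the
# uniform disc (R^2 / 2) -- exact zero centroid, matched second moment.
# Larger n: sunflower (Vogel spiral) coverage of the disc, de-biased by
# subtracting the sample centroid and rescaled to the disc's rms radius, so
# dense sampling keeps the same first and second moments.
aperture_sample_points <- function(model) {
  n <- model$aperture_samples
  r_disc <- effective_pinhole_diameter(model$collimator) / 2
  if (n == 1 || r_disc == 0)
    return(matrix(0, nrow = n, ncol = 2))
  if (n <= 12) {
    if (n %% 2 == 0) {
      ang <- 2 * pi * (seq_len(n) - 1) / n
      r <- r_disc / sqrt(2)
      return(cbind(r * cos(ang), r * sin(ang)))
    }
    m <- n - 1
    ang <- 2 * pi * (seq_len(m) - 1) / m
    r <- r_disc * sqrt(n / (2 * m))
    return(rbind(c(0, 0), cbind(r * cos(ang), r * sin(ang))))
  }
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- r_disc * sqrt((k - 0.5) / n)
  pts <- cbind(r * cos(k * golden), r * sin(k * golden))
  pts <- sweep(pts, 2, colMeans(pts))
  pts * r_disc / sqrt(2 * mean(pts[, 1]^2 + pts[, 2]^2))
}
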