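#' Axial-mean transverse slice
#'
#' Averages the central fraction of axial slices into one 2-D transverse
#' image (suppresses noise without affecting transverse resolution when the
#' features are z-invariant).
#'
#' @param volume A [volume_image()].
#' @param fraction Central fraction of slices to average (default 1/3).
#' @return A list with `values` (nx x ny matrix), `pixel_size` (mm, length
#'   2) and `origin` (mm, length 2); class `plane_image`.
#' @export
axial_mean_slice <- function(volume, fraction = 1 / 3) {
  stopifnot(inherits(volume, "volume_image"), fraction > 0, fraction <= 1)
  nz <- dim(volume$values)[3]
  nkeep <- max(1L, round(nz * fraction))
  k0 <- floor((nz - nkeep) / 2) + 1
  sl <- apply(volume$values[, , k0:(k0 + nkeep - 1), drop = FALSE], c(1, 2), mean)
  structure(list(values = sl, pixel_size = volume$voxel_size[1:2],
                 origin = volume$origin[1:2]),
            class = "plane_image")
}

# Bilinear sample of a plane_image at physical points (n x 2 matrix, mm).
bilinear_sample <- function(img, pts) {
  d <- dim(img$values)
  fx <- (pts[, 1] - img$origin[1]) / img$pixel_size[1] - 0.5
  fy <- (pts[, 2] - img$origin[2]) / img$pixel_size[2] - 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  dx <- fx - i0; dy <- fy - j0
  get <- function(ii, jj) {
    v <- rep(0, length(ii))
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1
    v[ok] <- img$values[cbind(ii[ok] + 1, jj[ok] + 1)]
    v
  }
  get(i0, j0) * (1 - dx) * (1 - dy) + get(i0 + 1, j0) * dx * (1 - dy) +
    get(i0, j0 + 1) * (1 - dx) * dy + get(i0 + 1, j0 + 1) * dx * dy
}

#' Line profile through a 2-D image
#'
#' Bilinear samples at `n_samples` uniform points along the segment from
#' `p0` to `p1` (physical mm coordinates).
#'
#' @param img A `plane_image` (see [axial_mean_slice()]).
#' @param p0,p1 Segment endpoints, mm (length 2).
#' @param n_samples Number of samples (default 200).
#' @return A list with `values`, `spacing` (mm between samples) and
#'   `positions` (mm along the segment from `p0`).
#' @export
line_profile <- function(img, p0, p1, n_samples = 200) {
  stopifnot(inherits(img, "plane_image"), length(p0) == 2, length(p1) == 2,
            n_samples >= 2)
  lims_lo <- img$origin
  lims_hi <- img$origin + dim(img$values) * img$pixel_size
  for (p in list(p0, p1))
    if (any(p < lims_lo - 1e-9) || any(p > lims_hi + 1e-9))
      stop("out-of-bounds: profile endpoint outside the image")
  t <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  len <- sqrt(sum((p1 - p0)^2))
  list(values = bilinear_sample(img, pts), spacing = len / (n_samples - 1),
       positions = t * len)
}

#' FWHM of a peaked profile
#'
#' Background is the mean of the outer 10% of samples on each side; the
#' width is measured at background + (max - background) / 2 with linear
#' interpolation of the two crossings flanking the (unique, interior)
#' maximum.
#'
#' @param values Sampled profile values.
#' @param spacing Sample spacing, mm.
#' @return FWHM in mm.
#' @export
fwhm <- function(values, spacing) {
  n <- length(values)
  if (n < 5) stop("no-peak: profile too short")
  ntail <- max(1L, floor(n * 0.1))
  bg <- mean(c(values[seq_len(ntail)], values[seq(n - ntail + 1, n)]))
  imax <- which.max(values)
  if (imax <= ntail || imax > n - ntail)
    stop("no-peak: maximum lies at the profile boundary")
  peak <- values[imax]
  if (peak <= bg + .Machine$double.eps * (abs(bg) + 1))
    stop("no-peak: profile has no peak above background")
  half <- bg + (peak - bg) / 2
  # left crossing
  li <- imax
  while (li > 1 && values[li] > half) li <- li - 1
  if (values[li] > half) stop("no-peak: left half-maximum crossing not found")
  lx <- li + (half - values[li]) / (values[li + 1] - values[li])
  # right crossing
  ri <- imax
  while (ri < n && values[ri] > half) ri <- ri + 1
  if (values[ri] > half) stop("no-peak: right half-maximum crossing not found")
  rx <- ri - (half - values[ri]) / (values[ri - 1] - values[ri])
  (rx - lx) * spacing
}

#' Peak-valley contrast along a profile crossing several features
#'
#' Locates one peak per expected feature centre (maximum within half a
#' feature pitch of the centre) and the valley between each adjacent pair of
#' peaks; returns `mean(valleys) / mean(peaks)`, clipped to `[0, 1]`. If
#' fewer than two feature centres fall on the profile the signal is
#' unresolvable and 1.0 is returned.
#'
#' @param profile A profile list from [line_profile()].
#' @param centre_positions Expected feature-centre positions along the
#'   profile, mm from its start.
#' @param pitch Centre-to-centre feature spacing, mm.
#' @return Contrast ratio in `[0, 1]` (0 = fully separated, 1 = flat).
#' @export
peak_valley_contrast <- function(profile, centre_positions, pitch) {
  v <- profile$values; pos <- profile$positions
  centre_positions <- sort(centre_positions)
  keep <- centre_positions >= min(pos) & centre_positions <= max(pos)
  centre_positions <- centre_positions[keep]
  if (length(centre_positions) < 2) return(1.0)
  peaks <- numeric(length(centre_positions))
  peak_at <- numeric(length(centre_positions))
  for (i in seq_along(centre_positions)) {
    win <- which(abs(pos - centre_positions[i]) <= pitch / 2)
    if (length(win) == 0) return(1.0)
    peaks[i] <- max(v[win])
    peak_at[i] <- pos[win[which.max(v[win])]]
  }
  valleys <- numeric(length(centre_positions) - 1)
  for (i in seq_len(length(centre_positions) - 1)) {
    between <- which(pos > peak_at[i] & pos < peak_at[i + 1])
    if (length(between) == 0) return(1.0)
    valleys[i] <- min(v[between])
  }
  if (mean(peaks) <= 0) return(1.0)
  min(max(mean(valleys) / mean(peaks), 0), 1)
}

# Contrast for one descriptor row (>= 2 collinear feature centres): profile
# along the row's line, extended by 3/4 pitch beyond the end centres,
# clipped to the image.
row_contrast <- function(img, row, pitch, samples_per_mm = 20) {
  n <- nrow(row)
  dirv <- row[n, ] - row[1, ]
  len <- sqrt(sum(dirv^2))
  u <- dirv / len
  ext <- 0.75 * pitch
  p0 <- row[1, ] - u * ext
  p1 <- row[n, ] + u * ext
  lims_lo <- img$origin + 1e-6
  lims_hi <- img$origin + dim(img$values) * img$pixel_size - 1e-6
  p0 <- pmin(pmax(p0, lims_lo), lims_hi)
  p1 <- pmin(pmax(p1, lims_lo), lims_hi)
  nsamp <- max(50L, ceiling(sqrt(sum((p1 - p0)^2)) * samples_per_mm))
  prof <- line_profile(img, p0, p1, nsamp)
  centre_pos <- apply(row, 1, function(c2) sum((c2 - p0) * u))
  peak_valley_contrast(prof, centre_pos, pitch)
}

#' Limiting resolution of a reconstruction
#'
#' Scores a reconstructed phantom volume against its ground-truth
#' descriptor. The volume is averaged over the central axial third, then for
#' each feature size the descriptor's rows of collinear feature centres are
#' profiled and the peak-valley contrast computed. A feature size is
#' classified resolved when its aggregated contrast (mean over rows for
#' hot-rod sectors; maximum over adjacent pairs for capillaries) is below
#' `criterion`. The limiting resolution is the smallest resolved feature
#' size.
#'
#' @param recon A [volume_image()] on the phantom's grid.
#' @param descriptor Ground-truth descriptor (attribute of [make_jaszczak()]
#'   / [make_capillary()] volumes, or [read_descriptor()]).
#' @param criterion Valley/peak threshold below which a feature counts as
#'   resolved (default 0.735).
#' @param axial_fraction Central axial fraction averaged before profiling.
#' @return An object of class `resolution_report`: `per_feature_contrast`,
#'   `resolved` (named by feature size, mm), and `limiting_resolution` (mm;
#'   `NA` if nothing is resolved).
#' @export
limiting_resolution <- function(recon, descriptor, criterion = 0.735,
                                axial_fraction = 1 / 3) {
  stopifnot(inherits(recon, "volume_image"))
  if (is.null(descriptor$features))
    stop("geometry error: descriptor carries no feature list")
  img <- axial_mean_slice(recon, axial_fraction)
  half_ext <- dim(img$values) * img$pixel_size / 2
  for (f in descriptor$features) {
    lim_mat <- matrix(half_ext + 1e-6, nrow(f$centres), 2, byrow = TRUE)
    if (any(abs(f$centres) > lim_mat))
      stop("geometry error: descriptor features lie outside the volume")
  }
  sizes <- vapply(descriptor$features, function(f) f$size, numeric(1))
  contrast <- setNames(numeric(length(sizes)), format(sizes))
  resolved <- setNames(logical(length(sizes)), format(sizes))
  for (i in seq_along(descriptor$features)) {
    f <- descriptor$features[[i]]
    cr <- vapply(f$rows, function(r) row_contrast(img, r, f$pitch), numeric(1))
    agg <- if (identical(f$aggregate, "max")) max(cr) else mean(cr)
    contrast[i] <- agg
    resolved[i] <- agg < criterion
  }
  lim <- if (any(resolved)) min(sizes[resolved]) else NA_real_
  structure(list(per_feature_contrast = contrast,
                 resolved = resolved,
                 feature_sizes = sizes,
                 criterion = criterion,
                 limiting_resolution = lim),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("resolution_report (criterion", x$criterion, ")\n")
  for (i in seq_along(x$feature_sizes))
    cat(sprintf("  %.2f mm: contrast %.3f -> %s\n", x$feature_sizes[i],
                x$per_feature_contrast[i],
                if (x$resolved[i]) "resolved" else "not resolved"))
  cat("  limiting resolution:",
      if (is.na(x$limiting_resolution)) "none"
      else sprintf("%.2f mm", x$limiting_resolution), "\n")
  invisible(x)
}

#' Point-source FWHM through the full pipeline
#'
#' Simulates a point source with the full system model (finite aperture,
#' detector blur), reconstructs it with plain MLEM (no smoothing) under the
#' purely geometric model -- ideal pinhole, no intrinsic blur -- and
#' measures the transverse FWHM of the reconstructed blob (mean of the x
#' and y profiles through the hottest voxel). Reconstructing without
#' resolution modelling keeps the acquisition blur in the image instead of
#' deconvolving it, which is the standard way to characterize system (as
#' opposed to algorithmic) resolution; the analytic counterpart is
#' [predicted_system_resolution()].
#'
#' @param model A [system_model()] used for the simulation.
#' @param grid A [volume_image()] template.
#' @param position Point position, mm (default slightly off-centre to avoid
#'   gridding symmetry artefacts).
#' @param n_iterations MLEM iterations (default 20).
#' @param exposure,calibration Simulation constants.
#' @return FWHM in mm.
#' @export
measure_psf_fwhm <- function(model, grid, position = c(1.0, 0.6, 0),
                             n_iterations = 20, exposure = 60,
                             calibration = 1) {
  # a point input exposes aperture discretization directly, so the
  # simulation model gets a densely sampled aperture disc
  m_sim <- system_model(model$detector, model$collimator, model$geometry,
                        aperture_samples = max(model$aperture_samples, 37L))
  src <- make_point_sources(matrix(position, 1), 1, grid)
  proj <- forward_project(src, m_sim, exposure, calibration)
  det_geo <- model$detector
  det_geo$intrinsic_fwhm <- 1e-9
  m_geo <- system_model(det_geo, model$collimator, model$geometry,
                        aperture_samples = 1)
  st <- recon_settings(n_iterations = n_iterations, n_subsets = 1,
                       smooth_width = 0, track_likelihood = FALSE)
  proj$fingerprint <- ""  # deliberate model mismatch: no resolution modelling
  rec <- osem_reconstruct(proj, m_geo, grid, st)
  idx <- which(rec$values == max(rec$values), arr.ind = TRUE)[1, ]
  xs <- axis_centres(rec, 1); ys <- axis_centres(rec, 2)
  img <- structure(list(values = rec$values[, , idx[3]],
                        pixel_size = rec$voxel_size[1:2],
                        origin = rec$origin[1:2]), class = "plane_image")
  cx <- xs[idx[1]]; cy <- ys[idx[2]]
  lo <- img$origin + 1e-6
  hi <- img$origin + dim(img$values) * img$pixel_size - 1e-6
  px <- line_profile(img, c(lo[1], cy), c(hi[1], cy),
                     n_samples = 4 * dim(img$values)[1])
  py <- line_profile(img, c(cx, lo[2]), c(cx, hi[2]),
                     n_samples = 4 * dim(img$values)[2])
  mean(c(fwhm(px$values, px$spacing), fwhm(py$values, py$spacing)))
}
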