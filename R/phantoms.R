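#' Hot-rod (Jaszczak) phantom specification
#'
#' Four sectors of activity-filled rods of graded diameter arranged in a
#' cylinder; within each sector the gap between rod borders equals the rod
#' diameter (centre spacing = 2 d). The smallest sector whose rods are
#' separable in a reconstruction defines the limiting resolution.
#'
#' @param sector_diameters Rod diameters in mm, one per 90-degree sector.
#' @param cylinder_diameter Outer cylinder diameter, mm.
#' @param cylinder_height Rod length / cylinder height, mm.
#' @param concentration Activity concentration in the rods, MBq/mL
#'   (default 37, i.e. 1 mCi/mL).
#' @return An object of class `jaszczak_spec`.
#' @export
jaszczak_spec <- function(sector_diameters = c(0.5, 1.0, 2.0, 1.5),
                          cylinder_diameter = 28, cylinder_height = 30,
                          concentration = 37) {
  stopifnot(length(sector_diameters) == 4, all(sector_diameters > 0),
            cylinder_diameter > 2 * max(sector_diameters),
            cylinder_height > 0, concentration > 0)
  structure(list(sector_diameters = sector_diameters,
                 cylinder_diameter = cylinder_diameter,
                 cylinder_height = cylinder_height,
                 concentration = concentration),
            class = "jaszczak_spec")
}

#' Capillary-triangle phantom specification
#'
#' Six parallel filled capillaries stacked in a triangle (rows of 3, 2, 1).
#' Adjacent lumens are separated by `edge_gap` mm of wall, so the
#' centre-to-centre pitch is `inner_diameter + edge_gap`.
#'
#' @param n_capillaries Number of capillaries (6).
#' @param inner_diameter Lumen diameter, mm (default 1.0).
#' @param edge_gap Gap between lumen borders of contiguous capillaries, mm
#'   (default 0.5).
#' @param length Capillary length, mm.
#' @param concentration Activity concentration, MBq/mL (default 37).
#' @return An object of class `capillary_spec`.
#' @export
capillary_spec <- function(n_capillaries = 6, inner_diameter = 1.0,
                           edge_gap = 0.5, length = 30, concentration = 37) {
  stopifnot(n_capillaries == 6, inner_diameter > 0, edge_gap > 0,
            length > 0, concentration > 0)
  structure(list(n_capillaries = as.integer(n_capillaries),
                 inner_diameter = inner_diameter, edge_gap = edge_gap,
                 length = length, concentration = concentration),
            class = "capillary_spec")
}

# Rod layout for one hot-rod sector: hexagonal packing with centre pitch 2 d,
# rows perpendicular to the sector bisector, everything kept clear of the
# sector boundaries and the cylinder wall. Returns centres plus per-row
# grouping used by the resolution metrics.
sector_layout <- function(d, sector_angle_deg, cyl_radius) {
  pitch <- 2 * d
  row_step <- pitch * sqrt(3) / 2
  r_min <- max(2.5, 2 * d)          # keep clear of the cylinder centre
  r_max <- cyl_radius - d           # keep clear of the wall
  th <- sector_angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  centres <- NULL; rows <- list()
  j <- 0
  repeat {
    r <- r_min + j * row_step
    if (r > r_max) break
    off <- if (j %% 2 == 1) pitch / 2 else 0
    t_max <- r * tan(pi / 4) - 1.5 * d  # stay inside the 90-degree wedge
    ks <- seq(-floor((t_max + off) / pitch), floor((t_max - off) / pitch))
    ts <- ks * pitch + off
    ts <- ts[abs(ts) <= t_max]
    if (length(ts) > 0) {
      local <- cbind(r, ts)
      keep <- sqrt(local[, 1]^2 + local[, 2]^2) <= r_max
      local <- local[keep, , drop = FALSE]
      if (nrow(local) > 0) {
        glob <- t(rot %*% t(local))
        centres <- rbind(centres, glob)
        rows[[length(rows) + 1]] <- glob
      }
    }
    j <- j + 1
  }
  list(centres = centres, rows = rows)
}

# Occupancy-weighted rendering of circles (cross-sections of z-parallel
# cylinders) on the volume's in-plane grid, with sub x sub sub-sampling of
# each voxel face for partial-volume handling. Returns an nx x ny matrix of
# occupancy fractions in [0, 1].
render_circles <- function(vol, centres, radii, sub = 3) {
  xs <- axis_centres(vol, 1); ys <- axis_centres(vol, 2)
  vx <- vol$voxel_size[1]; vy <- vol$voxel_size[2]
  occ <- matrix(0, length(xs), length(ys))
  offs <- (seq_len(sub) - (sub + 1) / 2) / sub
  for (ox in offs) for (oy in offs) {
    gx <- xs + ox * vx
    gy <- ys + oy * vy
    for (ci in seq_len(nrow(centres))) {
      dx2 <- (gx - centres[ci, 1])^2
      dy2 <- (gy - centres[ci, 2])^2
      occ <- occ + (outer(dx2, dy2, "+") <= radii[ci]^2)
    }
  }
  pmin(occ / (sub * sub), 1)
}

# z occupancy fraction of each slice for a feature spanning [-h/2, h/2].
z_occupancy <- function(vol, height) {
  zs <- axis_centres(vol, 3)
  vz <- vol$voxel_size[3]
  lo <- pmax(zs - vz / 2, -height / 2)
  hi <- pmin(zs + vz / 2, height / 2)
  pmax(hi - lo, 0) / vz
}

extrude <- function(vol, occ2d, zfrac, value) {
  v <- vol$values
  for (k in seq_along(zfrac))
    if (zfrac[k] > 0) v[, , k] <- v[, , k] + value * occ2d * zfrac[k]
  volume_image(v, vol$voxel_size, vol$origin)
}

#' Voxelize a hot-rod phantom
#'
#' Renders the rods of a [jaszczak_spec()] into the template grid. Rod
#' interiors carry the specified concentration; the acrylic and exterior are
#' zero. Boundary voxels get the concentration scaled by their sub-sampled
#' occupancy fraction. The returned volume carries the ground-truth
#' descriptor (`attr(x, "descriptor")`): rod centres, per-sector rows and
#' sizes, as used by [limiting_resolution()].
#'
#' @param spec A [jaszczak_spec()].
#' @param grid A [volume_image()] template defining the voxel grid.
#' @return A [volume_image()] with a `descriptor` attribute.
#' @export
make_jaszczak <- function(spec, grid) {
  stopifnot(inherits(spec, "jaszczak_spec"), inherits(grid, "volume_image"))
  if (max(grid$voxel_size[1:2]) > min(spec$sector_diameters) / 2)
    stop("resolution-insufficient: voxel size must be <= smallest rod diameter / 2")
  R <- spec$cylinder_diameter / 2
  vol <- volume_image(array(0, dim(grid$values)), grid$voxel_size, grid$origin)
  zfrac <- z_occupancy(vol, spec$cylinder_height)
  features <- list()
  sector_angles <- 45 + 90 * (seq_along(spec$sector_diameters) - 1)
  for (si in seq_along(spec$sector_diameters)) {
    d <- spec$sector_diameters[si]
    lay <- sector_layout(d, sector_angles[si], R)
    if (is.null(lay$centres) || nrow(lay$centres) == 0)
      stop(sprintf("no rods of %.2f mm fit the cylinder", d))
    occ <- render_circles(vol, lay$centres, rep(d / 2, nrow(lay$centres)))
    vol <- extrude(vol, occ, zfrac, spec$concentration)
    features[[si]] <- list(size = d, pitch = 2 * d,
                           centres = lay$centres,
                           rows = Filter(function(r) nrow(r) >= 3, lay$rows),
                           aggregate = "mean")
  }
  desc <- list(type = "jaszczak", cylinder_diameter = spec$cylinder_diameter,
               cylinder_height = spec$cylinder_height,
               concentration = spec$concentration, features = features)
  attr(vol, "descriptor") <- desc
  vol
}

#' Voxelize a capillary-triangle phantom
#'
#' Six z-parallel filled cylinders in triangular packing (rows of 3, 2, 1),
#' centre pitch `inner_diameter + edge_gap`, centred on the rotation axis.
#' The `descriptor` attribute records every adjacent capillary pair; a pair
#' counts as resolved only if the valley between the two lumens dips below
#' the contrast criterion.
#'
#' @param spec A [capillary_spec()].
#' @param grid A [volume_image()] template.
#' @return A [volume_image()] with a `descriptor` attribute.
#' @export
make_capillary <- function(spec, grid) {
  stopifnot(inherits(spec, "capillary_spec"), inherits(grid, "volume_image"))
  if (max(grid$voxel_size[1:2]) > spec$edge_gap / 2)
    stop("resolution-insufficient: voxel size must be <= edge gap / 2")
  p <- spec$inner_diameter + spec$edge_gap
  h <- p * sqrt(3) / 2
  centres <- rbind(c(-p, 0), c(0, 0), c(p, 0),
                   c(-p / 2, h), c(p / 2, h),
                   c(0, 2 * h))
  centres[, 2] <- centres[, 2] - 2 * h / 3  # centroid on the rotation axis
  vol <- volume_image(array(0, dim(grid$values)), grid$voxel_size, grid$origin)
  occ <- render_circles(vol, centres, rep(spec$inner_diameter / 2, 6))
  zfrac <- z_occupancy(vol, spec$length)
  vol <- extrude(vol, occ, zfrac, spec$concentration)
  adj <- list(c(1, 2), c(2, 3), c(1, 4), c(2, 4), c(2, 5), c(3, 5),
              c(4, 5), c(4, 6), c(5, 6))
  rows <- lapply(adj, function(ij) centres[ij, , drop = FALSE])
  features <- list(list(size = spec$edge_gap, pitch = p, centres = centres,
                        rows = rows, aggregate = "max"))
  desc <- list(type = "capillary", inner_diameter = spec$inner_diameter,
               edge_gap = spec$edge_gap, length = spec$length,
               concentration = spec$concentration, features = features)
  attr(vol, "descriptor") <- desc
  vol
}

#' Point-source volume
#'
#' Places single-voxel impulses at the given positions. Each impulse carries
#' `activity / voxel_volume` so that total activity integrates to the listed
#' activities.
#'
#' @param positions n x 3 matrix of positions in mm (target frame).
#' @param activities Length-n activities (arbitrary units).
#' @param grid A [volume_image()] template.
#' @return A [volume_image()].
#' @export
make_point_sources <- function(positions, activities, grid) {
  stopifnot(inherits(grid, "volume_image"))
  positions <- matrix(positions, ncol = 3)
  if (nrow(positions) == 0)
    return(volume_image(array(0, dim(grid$values)), grid$voxel_size, grid$origin))
  stopifnot(length(activities) == nrow(positions), all(activities >= 0))
  d <- dim(grid$values)
  v <- array(0, d)
  vvol <- prod(grid$voxel_size)
  for (i in seq_len(nrow(positions))) {
    idx <- floor((positions[i, ] - grid$origin) / grid$voxel_size) + 1
    if (any(idx < 1) || any(idx > d))
      stop("out-of-bounds: point source position outside the grid")
    v[idx[1], idx[2], idx[3]] <- v[idx[1], idx[2], idx[3]] + activities[i] / vvol
  }
  volume_image(v, grid$voxel_size, grid$origin)
}

#' Write a phantom ground-truth descriptor as JSON
#'
#' @param volume A phantom volume carrying a `descriptor` attribute.
#' @param path Output path for the JSON descriptor.
#' @return `path`, invisibly.
#' @export
write_descriptor <- function(volume, path) {
  desc <- attr(volume, "descriptor")
  if (is.null(desc)) stop("volume carries no ground-truth descriptor")
  jsonlite::write_json(descriptor_to_json(desc), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a phantom ground-truth descriptor
#'
#' @param path JSON descriptor path written by [write_descriptor()].
#' @return The descriptor list.
#' @export
read_descriptor <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such descriptor file: ", path)
  descriptor_from_json(jsonlite::read_json(path, simplifyVector = FALSE))
}

descriptor_to_json <- function(desc) {
  desc$features <- lapply(desc$features, function(f) {
    f$centres <- unname(apply(f$centres, 1, as.numeric, simplify = FALSE))
    f$rows <- lapply(f$rows, function(r)
      unname(apply(r, 1, as.numeric, simplify = FALSE)))
    f
  })
  desc
}

descriptor_from_json <- function(js) {
  js <- lapply(js, function(x) if (is.list(x)) x else x)
  js$features <- lapply(js$features, function(f) {
    list(size = as.numeric(f$size), pitch = as.numeric(f$pitch),
         centres = do.call(rbind, lapply(f$centres,
                                         function(p) as.numeric(unlist(p)))),
         rows = lapply(f$rows, function(r)
           do.call(rbind, lapply(r, function(p) as.numeric(unlist(p))))),
         aggregate = as.character(f$aggregate))
  })
  for (k in setdiff(names(js), "features"))
    if (is.list(js[[k]]) && length(js[[k]]) == 1) js[[k]] <- js[[k]][[1]]
  js
}
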