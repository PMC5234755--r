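#' 3-D activity volume
#'
#' A non-negative voxel grid with physical voxel size and origin. Voxel
#' `(i, j, k)` (1-based) has its centre at `origin + (c(i,j,k) - 0.5) *
#' voxel_size`; with the default origin the grid is centred on the rotation
#' axis (z) at the axial mid-plane.
#'
#' @param values 3-D numeric array (finite, >= 0).
#' @param voxel_size Voxel edge lengths in mm; scalar or length 3.
#' @param origin Position of the grid corner in mm (length 3). Default
#'   centres the grid on (0, 0, 0).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, voxel_size, origin = NULL) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (any(!is.finite(values)) || any(values < 0))
    stop("volume values must be finite and non-negative")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  stopifnot(length(origin) == 3)
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Empty volume over a centred field of view
#'
#' @param fov Field-of-view extents in mm (length 3 or scalar).
#' @param voxel_size Voxel size in mm (scalar or length 3).
#' @return A zero-filled [volume_image()] centred on the origin.
#' @export
volume_template <- function(fov, voxel_size) {
  fov <- rep_len(as.numeric(fov), 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  dims <- pmax(1L, as.integer(round(fov / voxel_size)))
  volume_image(array(0, dims), voxel_size)
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_image %d x %d x %d voxels @ (%.4g, %.4g, %.4g) mm, total activity %.4g\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              sum(x$values) * prod(x$voxel_size)))
  invisible(x)
}

# Voxel-centre coordinates along one axis.
axis_centres <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size[axis]
}

#' Gaussian smoothing of a volume
#'
#' Separable 3-D Gaussian convolution with the kernel width given as a FWHM
#' in voxels (sigma = width / 2.3548). Boundaries are handled by mirror
#' reflection, so the total sum is preserved. `width = 0` is the identity.
#'
#' @param volume A [volume_image()].
#' @param width Kernel FWHM in voxels (>= 0).
#' @return Smoothed [volume_image()].
#' @export
gaussian_smooth <- function(volume, width) {
  stopifnot(inherits(volume, "volume_image"))
  if (!is.numeric(width) || length(width) != 1 || width < 0)
    stop("settings error: smoothing width must be a single number >= 0")
  if (width == 0) return(volume)
  sigma <- width / (2 * sqrt(2 * log(2)))
  v <- volume$values
  for (axis in 1:3) {
    m <- conv_matrix(dim(v)[axis], sigma, boundary = "mirror")
    v <- apply_axis_matrix(v, m, axis)
  }
  v[v < 0] <- 0  # clip tiny negative round-off
  volume_image(v, volume$voxel_size, volume$origin)
}

# Dense one-axis convolution matrix for a normalized Gaussian kernel
# (sigma in samples). boundary = "mirror" folds mass back (columns sum to 1,
# not symmetric); "zero" truncates (symmetric Toeplitz, self-adjoint).
conv_matrix <- function(n, sigma, boundary = c("mirror", "zero")) {
  boundary <- match.arg(boundary)
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  taps <- stats::dnorm(seq(-r, r), sd = sigma)
  taps <- taps / sum(taps)
  m <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + seq(-r, r)
    if (boundary == "mirror") {
      # reflect about edge sample centres: ..., 3, 2, 1, 2, 3, ...
      idx <- ifelse(idx < 1, 2 - idx, idx)
      idx <- ifelse(idx > n, 2 * n - idx, idx)
      idx <- pmin(pmax(idx, 1L), n)
      for (t in seq_along(idx)) m[idx[t], j] <- m[idx[t], j] + taps[t]
    } else {
      keep <- idx >= 1 & idx <= n
      m[cbind(idx[keep], j)] <- m[cbind(idx[keep], j)] + taps[keep]
    }
  }
  m
}

# Multiply a convolution matrix along one axis of a 3-D array.
apply_axis_matrix <- function(a, m, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  res <- m %*% matrix(ap, nrow = dp[1])
  dim(res) <- dp
  aperm(res, order(perm))
}

# Trilinear resampling of a volume rotated by `angle` degrees about +z
# (values outside the original grid read as 0). Used for rotation-
# equivariance checks; the projector itself never resamples the volume.
rotate_volume <- function(volume, angle) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$values)
  xs <- axis_centres(volume, 1); ys <- axis_centres(volume, 2)
  th <- -angle * pi / 180  # sample source at inverse rotation
  g <- expand.grid(x = xs, y = ys)
  xs0 <- g$x * cos(th) - g$y * sin(th)
  ys0 <- g$x * sin(th) + g$y * cos(th)
  fx <- (xs0 - volume$origin[1]) / volume$voxel_size[1] - 0.5
  fy <- (ys0 - volume$origin[2]) / volume$voxel_size[2] - 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  dx <- fx - i0; dy <- fy - j0
  out <- array(0, d)
  val_at <- function(ii, jj) {
    ok <- ii >= 0 & ii <= d[1] - 1 & jj >= 0 & jj <= d[2] - 1
    sel <- matrix(0, length(ii), 1)
    lin <- (ii + 1) + d[1] * jj
    plane <- matrix(0, length(ii), d[3])
    for (k in seq_len(d[3])) {
      v <- rep(0, length(ii))
      v[ok] <- volume$values[lin[ok] + d[1] * d[2] * (k - 1)]
      plane[, k] <- v
    }
    plane
  }
  acc <- val_at(i0, j0) * ((1 - dx) * (1 - dy)) +
    val_at(i0 + 1, j0) * (dx * (1 - dy)) +
    val_at(i0, j0 + 1) * ((1 - dx) * dy) +
    val_at(i0 + 1, j0 + 1) * (dx * dy)
  out <- array(acc, d)
  out[out < 0] <- 0
  volume_image(out, volume$voxel_size, volume$origin)
}
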