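# Small system models and grids shared across tests. Kept deliberately
# tiny: the operators are exact at any scale, so correctness properties are
# checked on instances that run in milliseconds.

tiny_model <- function(aperture_samples = 3, n_projections = 4,
                       intrinsic_fwhm = 2, b = 10, f = 30,
                       detector_mm = 40, pitch = 2) {
  system_model(
    detector_spec(detector_mm, detector_mm, pixel_pitch = pitch,
                  intrinsic_fwhm = intrinsic_fwhm),
    collimator_spec(1, "lead"),
    acquisition_geometry(b, f, n_projections),
    aperture_samples = aperture_samples)
}

tiny_grid <- function(fov = 8, voxel = 1) volume_template(fov, voxel)

random_volume <- function(grid, seed = 1, sparsity = 0) {
  set.seed(seed)
  v <- grid
  vals <- runif(length(v$values))
  if (sparsity > 0) vals[runif(length(vals)) < sparsity] <- 0
  v$values[] <- vals
  v
}

# rat (7x, lead 1.5 mm) and mouse (9x, tungsten 0.5 mm) study configurations
# at desk scale
rat_model <- function(aperture_samples = 7) {
  system_model(detector_spec(224, 224, pixel_pitch = 1.75),
               collimator_spec(1.5, "lead"),
               acquisition_geometry(36, 252, 40),
               aperture_samples = aperture_samples)
}

mouse_model <- function(aperture_samples = 7) {
  system_model(detector_spec(160, 160, pixel_pitch = 1.25),
               collimator_spec(0.5, "tungsten"),
               acquisition_geometry(28, 252, 40),
               aperture_samples = aperture_samples)
}

# dense matrix of the forward operator, built by probing with unit vectors;
# the independent oracle for adjoint tests
dense_operator <- function(model, grid, exposure = 1) {
  nvox <- length(grid$values)
  npix <- model$detector$n_u * model$detector$n_v *
    length(model$geometry$angles)
  P <- matrix(0, npix, nvox)
  for (j in seq_len(nvox)) {
    g <- grid
    g$values[j] <- 1
    P[, j] <- as.numeric(forward_project(g, model, exposure)$frames)
  }
  P
}

# flood-fill count of 4-connected components in a binary matrix
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1) %% nrow(mask) + 1
      j <- (p - 1) %/% nrow(mask) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          q <- ii + (jj - 1) * nrow(mask)
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  cur
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(a^2))
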