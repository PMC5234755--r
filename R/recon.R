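#' Reconstruction settings
#'
#' @param n_iterations Full passes over all projections (default 20).
#' @param n_subsets Number of angle-interleaved projection subsets
#'   (default 4; 1 gives plain MLEM).
#' @param smooth_width FWHM of the inter-iteration Gaussian kernel, in
#'   reconstruction voxels (default 1.5; 0 disables smoothing).
#' @param smooth_every Apply the smoothing after every this many full
#'   iterations (default 2).
#' @param epsilon Relative floor applied to projected means before the ratio
#'   (default 1e-10; multiplied by `max(P x)`).
#' @param track_likelihood Record the Poisson log-likelihood after each full
#'   iteration (costs one extra forward projection per iteration).
#' @return An object of class `recon_settings`.
#' @export
recon_settings <- function(n_iterations = 20, n_subsets = 4,
                           smooth_width = 1.5, smooth_every = 2,
                           epsilon = 1e-10, track_likelihood = TRUE) {
  if (n_iterations < 1) stop("settings error: n_iterations must be >= 1")
  if (n_subsets < 1) stop("settings error: n_subsets must be >= 1")
  if (smooth_width < 0) stop("settings error: smooth_width must be >= 0")
  if (smooth_every < 1) stop("settings error: smooth_every must be >= 1")
  if (epsilon <= 0) stop("settings error: epsilon must be > 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 smooth_width = smooth_width,
                 smooth_every = as.integer(smooth_every),
                 epsilon = epsilon,
                 track_likelihood = isTRUE(track_likelihood)),
            class = "recon_settings")
}

# Angle-interleaved subsets: subset k contains angles k, k + S, k + 2S, ...
# (maximal angular coverage per sub-iteration; fixed order).
subset_indices <- function(n_angles, n_subsets) {
  if (n_subsets > n_angles)
    stop("settings error: more subsets than projection angles")
  lapply(seq_len(n_subsets), function(k) seq(k, n_angles, by = n_subsets))
}

#' One MLEM update
#'
#' The multiplicative expectation-maximization step for Poisson data:
#' `x' = (x / s) * P^T(y / max(P x, eps))`, where `s` is the sensitivity
#' map for the angles being used. Voxels with zero sensitivity stay zero.
#'
#' @param estimate Current estimate, a [volume_image()] (positive inside the
#'   sensitivity support).
#' @param data Measured [projection_set()] (all frames, or the frames of
#'   `subset` when given).
#' @param model A [system_model()].
#' @param sensitivity Sensitivity [volume_image()] matching `subset`
#'   (computed when omitted).
#' @param subset Optional integer angle indices.
#' @param epsilon Relative ratio floor.
#' @return Updated [volume_image()].
#' @export
mlem_update <- function(estimate, data, model, sensitivity = NULL,
                        subset = NULL, epsilon = 1e-10) {
  stopifnot(inherits(estimate, "volume_image"),
            inherits(data, "projection_set"),
            inherits(model, "system_model"))
  if (nzchar(data$fingerprint) &&
      !identical(data$fingerprint, model_fingerprint(model)))
    stop("geometry error: data fingerprint does not match the model")
  if (is.null(subset)) subset <- seq_along(model$geometry$angles)
  if (length(subset) != dim(data$frames)[3])
    stop("consistency error: subset length must equal frame count")
  if (is.null(sensitivity))
    sensitivity <- sensitivity_map(model, estimate, data$exposure,
                                   data$calibration, subset = subset)
  scale <- proj_scale(model, data$exposure, data$calibration) *
    prod(estimate$voxel_size)
  px <- forward_raw(estimate$values, estimate$voxel_size, estimate$origin,
                    model, subset, scale)
  mx <- max(px)
  if (mx <= 0 && sum(data$frames) > 0)
    stop("degenerate-start: estimate projects to zero but data are nonzero")
  floorv <- if (mx > 0) epsilon * mx else epsilon
  ratio <- data$frames / pmax(px, floorv)
  bp <- adjoint_raw(ratio, dim(estimate$values), estimate$voxel_size,
                    estimate$origin, model, subset, scale)
  s <- sensitivity$values
  upd <- estimate$values
  pos <- s > 0
  upd[pos] <- estimate$values[pos] / s[pos] * bp[pos]
  upd[!pos] <- 0
  upd[upd < 0] <- 0
  volume_image(upd, estimate$voxel_size, estimate$origin)
}

# Poisson log-likelihood of data y under means m (constant log(y!) dropped).
poisson_loglik <- function(y, m, floorv = 1e-12) {
  m <- pmax(m, floorv)
  sum(y * log(m)) - sum(m)
}

#' OSEM reconstruction
#'
#' Ordered-subset expectation maximization with periodic inter-iteration
#' Gaussian smoothing. With `n_subsets = 1` and `smooth_width = 0` the
#' result is identical to sequential MLEM updates. The estimate starts
#' uniform inside the sensitivity support at the count-matched level
#' `sum(y) / sum(s)`; each full iteration applies the multiplicative update
#' once per subset (subset-specific sensitivity), and after every
#' `smooth_every` full iterations the estimate is convolved with the
#' Gaussian of FWHM `smooth_width` voxels.
#'
#' @param data Measured [projection_set()].
#' @param model A [system_model()].
#' @param grid A [volume_image()] template for the reconstruction grid.
#' @param settings A [recon_settings()].
#' @param verbose Print per-iteration progress.
#' @return A [volume_image()]; attribute `loglik` holds the per-full-
#'   iteration Poisson log-likelihood trace when tracking is enabled.
#' @export
osem_reconstruct <- function(data, model, grid, settings = recon_settings(),
                             verbose = FALSE) {
  stopifnot(inherits(data, "projection_set"), inherits(model, "system_model"),
            inherits(grid, "volume_image"), inherits(settings, "recon_settings"))
  if (nzchar(data$fingerprint) &&
      !identical(data$fingerprint, model_fingerprint(model)))
    stop("geometry error: data fingerprint does not match the model")
  n_ang <- length(model$geometry$angles)
  if (dim(data$frames)[3] != n_ang)
    stop("consistency error: data must contain one frame per model angle")
  subsets <- subset_indices(n_ang, settings$n_subsets)
  sens <- lapply(subsets, function(ss)
    sensitivity_map(model, grid, data$exposure, data$calibration, subset = ss))
  s_tot <- Reduce(`+`, lapply(sens, function(s) s$values))
  support <- s_tot > 0
  init <- sum(data$frames) / sum(s_tot)
  x <- volume_image(array(ifelse(support, init, 0), dim(grid$values)),
                    grid$voxel_size, grid$origin)
  scale <- proj_scale(model, data$exposure, data$calibration) *
    prod(grid$voxel_size)
  loglik <- numeric(0)
  for (it in seq_len(settings$n_iterations)) {
    t0 <- proc.time()[["elapsed"]]
    for (si in seq_along(subsets)) {
      ss <- subsets[[si]]
      sub_data <- projection_set(data$frames[, , ss, drop = FALSE],
                                 data$pixel_pitch, data$angles[ss],
                                 data$exposure, data$fingerprint,
                                 counts = data$counts,
                                 calibration = data$calibration)
      x <- mlem_update(x, sub_data, model, sens[[si]], subset = ss,
                       epsilon = settings$epsilon)
    }
    if (settings$smooth_width > 0 && it %% settings$smooth_every == 0)
      x <- gaussian_smooth(x, settings$smooth_width)
    if (settings$track_likelihood) {
      px <- forward_raw(x$values, x$voxel_size, x$origin, model,
                        seq_len(n_ang), scale)
      loglik <- c(loglik, poisson_loglik(data$frames, px))
    }
    if (verbose)
      message(sprintf("iteration %d/%d%s (%.2f s)", it, settings$n_iterations,
                      if (settings$track_likelihood)
                        sprintf(", loglik %.6g", loglik[length(loglik)]) else "",
                      proc.time()[["elapsed"]] - t0))
  }
  if (settings$track_likelihood) attr(x, "loglik") <- loglik
  attr(x, "settings") <- settings
  x
}
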