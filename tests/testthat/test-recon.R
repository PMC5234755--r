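test_that("MLEM leaves self-consistent data at its fixed point", {
  m <- tiny_model()
  grid <- tiny_grid()
  # positive activity everywhere inside the support, away from edges
  x <- grid
  xs <- pinspect:::axis_centres(grid, 1)
  r2 <- outer(xs^2, xs^2, "+")
  for (k in 1:dim(x$values)[3])
    x$values[, , k] <- ifelse(r2 < 3^2, 1 + 0.5 * sin(xs), 0)
  y <- forward_project(x, m, exposure = 1)
  s <- sensitivity_map(m, grid, exposure = 1)
  x1 <- mlem_update(x, y, m, s)
  on_support <- s$values > 0 & x$values > 0
  expect_lt(max(abs(x1$values[on_support] - x$values[on_support]) /
                  x$values[on_support]), 1e-8)
})

test_that("each full MLEM update conserves total counts", {
  m <- tiny_model()
  grid <- tiny_grid()
  truth <- random_volume(grid, seed = 3)
  y <- add_poisson_noise(calibrate_counts(
    forward_project(truth, m, exposure = 1), 2e4), 11)
  s <- sensitivity_map(m, grid, exposure = 1, calibration = y$calibration)
  x <- grid
  x$values[] <- ifelse(s$values > 0, 1, 0)
  for (i in 1:3) {
    x <- mlem_update(x, y, m, s)
    expect_gte(min(x$values), 0)
    expect_equal(sum(s$values * x$values), sum(y$frames),
                 tolerance = 1e-6)
  }
})

test_that("Poisson log-likelihood is non-decreasing under pure MLEM", {
  m <- tiny_model()
  grid <- tiny_grid()
  truth <- random_volume(grid, seed = 5, sparsity = 0.5)
  y <- add_poisson_noise(calibrate_counts(
    forward_project(truth, m, exposure = 1), 2e4), 21)
  st <- recon_settings(n_iterations = 10, n_subsets = 1, smooth_width = 0,
                       track_likelihood = TRUE)
  rec <- osem_reconstruct(y, m, grid, st)
  ll <- attr(rec, "loglik")
  expect_length(ll, 10)
  expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
})

test_that("OSEM with one subset reproduces sequential MLEM exactly", {
  m <- tiny_model()
  grid <- tiny_grid()
  truth <- random_volume(grid, seed = 9)
  y <- add_poisson_noise(calibrate_counts(
    forward_project(truth, m, exposure = 1), 1e4), 31)
  st <- recon_settings(n_iterations = 4, n_subsets = 1, smooth_width = 0,
                       track_likelihood = FALSE)
  rec <- osem_reconstruct(y, m, grid, st)
  # manual MLEM chain from the same count-matched uniform start
  s <- sensitivity_map(m, grid, exposure = 1, calibration = y$calibration)
  x <- grid
  x$values[] <- ifelse(s$values > 0, sum(y$frames) / sum(s$values), 0)
  for (i in 1:4) x <- mlem_update(x, y, m, s)
  expect_equal(rec$values, x$values, tolerance = 1e-10)
})

test_that("reconstruction stays non-negative through OSEM plus smoothing", {
  m <- tiny_model(n_projections = 8)
  grid <- volume_template(c(8, 8, 4), 0.5)
  ph <- make_capillary(capillary_spec(inner_diameter = 1, edge_gap = 1,
                                      length = 3), grid)
  y <- add_poisson_noise(calibrate_counts(
    forward_project(ph, m, exposure = 1), 5e3), 41)
  rec <- osem_reconstruct(y, m, grid,
                          recon_settings(6, 4, smooth_width = 1.5,
                                         smooth_every = 2,
                                         track_likelihood = FALSE))
  expect_true(all(rec$values >= 0))
  expect_true(all(is.finite(rec$values)))
})

test_that("noiseless reconstructions keep improving with iterations", {
  m <- tiny_model(n_projections = 8)
  grid <- volume_template(c(8, 8, 4), 0.5)
  ph <- make_capillary(capillary_spec(inner_diameter = 1, edge_gap = 1,
                                      length = 3), grid)
  y <- forward_project(ph, m, exposure = 1)
  nrmse <- function(n_it) {
    rec <- osem_reconstruct(y, m, grid,
                            recon_settings(n_it, 1, smooth_width = 0,
                                           track_likelihood = FALSE))
    sqrt(mean((rec$values - ph$values)^2)) / sqrt(mean(ph$values^2))
  }
  expect_lt(nrmse(50), nrmse(5))
})

test_that("relabelling angles by one step rotates the reconstruction", {
  m <- tiny_model(aperture_samples = 3, n_projections = 8)
  grid <- volume_template(c(8, 8, 4), 0.25)
  # a smooth phantom keeps the trilinear-resampling comparison error small
  ph <- gaussian_smooth(
    make_capillary(capillary_spec(inner_diameter = 0.8, length = 3), grid), 3)
  y <- forward_project(ph, m, exposure = 1)
  st <- recon_settings(5, 1, smooth_width = 0, track_likelihood = FALSE)
  rec <- osem_reconstruct(y, m, grid, st)
  # shift the frames one angle step: frame recorded at angle k now claims
  # angle k+1, which is the same data for the target rotated by -step
  step <- 360 / 8
  y_shift <- y
  y_shift$frames <- y$frames[, , c(8, 1:7)]
  rec_shift <- osem_reconstruct(y_shift, m, grid, st)
  expect_lt(rel_rms(rec_shift$values,
                    pinspect:::rotate_volume(rec, -step)$values), 0.05)
})

test_that("Gaussian smoothing preserves mass and has the requested width", {
  grid <- volume_template(c(16, 16, 8), 0.5)
  x <- random_volume(grid, seed = 2)
  expect_identical(gaussian_smooth(x, 0)$values, x$values)
  sm <- gaussian_smooth(x, 2)
  expect_equal(sum(sm$values), sum(x$values), tolerance = 1e-6)
  # impulse response FWHM matches the requested width (in voxels)
  imp <- volume_template(c(16, 16, 8), 1)  # unit voxels
  imp$values[8, 8, 4] <- 1
  for (w in c(1.5, 3)) {
    blurred <- gaussian_smooth(imp, w)
    sl <- axial_mean_slice(blurred, 1 / 8)  # the impulse slice
    ctr <- pinspect:::axis_centres(imp, 1)[8]
    prof <- line_profile(sl, c(-7.9, ctr), c(7.9, ctr), n_samples = 400)
    expect_equal(fwhm(prof$values, prof$spacing), w, tolerance = 0.1 / w)
  }
  expect_error(gaussian_smooth(x, -1), "settings error")
})

test_that("degenerate inputs are rejected", {
  m <- tiny_model()
  grid <- tiny_grid()
  y <- calibrate_counts(forward_project(random_volume(grid), m,
                                        exposure = 1), 1e3)
  zero_start <- grid  # all-zero estimate
  expect_error(mlem_update(zero_start, y, m), "degenerate-start")
  expect_error(recon_settings(n_subsets = 0), "settings error")
  expect_error(osem_reconstruct(y, m, grid,
                                recon_settings(2, 5)), "settings error")
})
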