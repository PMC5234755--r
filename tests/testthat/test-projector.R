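test_that("forward projection is linear and preserves zero", {
  m <- tiny_model()
  grid <- tiny_grid()
  zero <- forward_project(grid, m, exposure = 1)
  expect_true(all(zero$frames == 0))
  x <- random_volume(grid, seed = 7)
  y1 <- forward_project(x, m, exposure = 1)
  x2 <- x; x2$values <- 2 * x$values
  y2 <- forward_project(x2, m, exposure = 1)
  expect_equal(y2$frames, 2 * y1$frames, tolerance = 1e-14)
  # additivity
  xb <- random_volume(grid, seed = 8)
  xs <- x; xs$values <- x$values + xb$values
  expect_equal(forward_project(xs, m, exposure = 1)$frames,
               y1$frames + forward_project(xb, m, exposure = 1)$frames,
               tolerance = 1e-12)
})

test_that("an on-axis source projects to the detector centre at every angle", {
  m <- tiny_model(n_projections = 8)
  grid <- volume_template(8, 0.5)
  # a source on the rotation axis (voxel centres straddle the axis, so use
  # four symmetric voxels around it)
  src <- make_point_sources(rbind(c(-.25, -.25, .25), c(.25, -.25, .25),
                                  c(-.25, .25, .25), c(.25, .25, .25)),
                            rep(1, 4), grid)
  ps <- forward_project(src, m, exposure = 1)
  nu <- m$detector$n_u
  us <- ((seq_len(nu)) - 0.5) * m$detector$pixel_pitch -
    nu * m$detector$pixel_pitch / 2
  for (a in seq_len(dim(ps$frames)[3])) {
    f <- ps$frames[, , a]
    cu <- sum(outer(us, rep(1, nu)) * f) / sum(f)
    expect_lt(abs(cu), 0.2 * m$detector$pixel_pitch)
  }
})

test_that("an off-axis source lands where the central-ray oracle predicts", {
  m <- rat_model()
  grid <- volume_template(c(10, 10, 4), 0.25)
  src <- make_point_sources(matrix(c(1.125, 0.125, 0.125), 1), 1, grid)
  pos <- c(1.125, 0.125, 0.125)  # voxel-centre aligned
  ps <- forward_project(src, m, exposure = 1)
  nu <- m$detector$n_u
  us <- (seq_len(nu) - 0.5) * m$detector$pixel_pitch -
    nu * m$detector$pixel_pitch / 2
  for (a in c(1, 11, 27)) {
    th <- m$geometry$angles[a]
    expected <- project_point(m, pos, th)
    f <- ps$frames[, , a]
    cu <- sum(outer(us, rep(1, nu)) * f) / sum(f)
    cv <- sum(outer(rep(1, nu), us) * f) / sum(f)
    expect_equal(cu, expected[1], tolerance = 0.1)
    expect_equal(cv, expected[2], tolerance = 0.1)
  }
})

test_that("back projection is the exact adjoint (dense-matrix oracle)", {
  m <- tiny_model(aperture_samples = 2, n_projections = 4,
                  detector_mm = 16, pitch = 2)
  grid <- tiny_grid(fov = 4, voxel = 0.5)  # 8^3 volume, 8x8 detector
  P <- dense_operator(m, grid)
  set.seed(42)
  for (trial in 1:3) {
    x <- random_volume(grid, seed = trial)
    y <- forward_project(x, m, exposure = 1)
    expect_equal(as.numeric(y$frames), as.numeric(P %*% as.numeric(x$values)),
                 tolerance = 1e-10)
    yr <- y; yr$frames[] <- runif(length(yr$frames))
    bt <- back_project(yr, m, grid)
    expect_equal(as.numeric(bt$values),
                 as.numeric(crossprod(P, as.numeric(yr$frames))),
                 tolerance = 1e-6)
    # inner-product identity <P x, y> = <x, P^T y>
    lhs <- sum(y$frames * yr$frames)
    rhs <- sum(x$values * bt$values)
    expect_equal(lhs, rhs, tolerance = 1e-6 * abs(lhs))
  }
})

test_that("sensitivity map equals back projection of ones and is positive", {
  m <- tiny_model()
  grid <- tiny_grid()
  s <- sensitivity_map(m, grid, exposure = 1)
  ones <- projection_set(array(1, c(m$detector$n_u, m$detector$n_v,
                                    length(m$geometry$angles))),
                         m$detector$pixel_pitch, m$geometry$angles, 1,
                         fingerprint = pinspect:::model_fingerprint(m))
  expect_equal(s$values, back_project(ones, m, grid)$values,
               tolerance = 1e-12)
  # strictly positive inside the imaged cylinder
  xs <- pinspect:::axis_centres(grid, 1)
  inside <- which(outer(xs^2, xs^2, "+") < (max_target_diameter(m) / 2)^2,
                  arr.ind = TRUE)
  mid <- dim(grid$values)[3] / 2
  expect_true(all(s$values[cbind(inside, mid)] > 0))
  # linear in exposure
  s2 <- sensitivity_map(m, grid, exposure = 2)
  expect_equal(s2$values, 2 * s$values, tolerance = 1e-12)
})

test_that("poisson simulation is reproducible and unbiased", {
  m <- tiny_model()
  grid <- tiny_grid()
  ps <- forward_project(random_volume(grid), m, exposure = 1)
  # zero mean -> zero counts
  zero <- ps; zero$frames[] <- 0
  expect_true(all(add_poisson_noise(zero, 5)$frames == 0))
  # determinism
  n1 <- add_poisson_noise(ps, 123)
  n2 <- add_poisson_noise(ps, 123)
  expect_identical(n1$frames, n2$frames)
  expect_false(identical(n1$frames, add_poisson_noise(ps, 124)$frames))
  # integer counts
  expect_true(all(n1$frames == round(n1$frames)))
  # mean of 1e4 draws at expectation 100 within 3 standard errors (0.3)
  flat <- projection_set(array(100, c(50, 50, 4)), 1, c(0, 90, 180, 270), 1)
  draws <- add_poisson_noise(flat, 99)
  expect_equal(mean(draws$frames), 100, tolerance = 0.3 / 100)
  expect_error(add_poisson_noise(structure(list(frames = array(-1, c(2, 2, 1)),
                                                pixel_pitch = 1,
                                                angles = 0, exposure = 1),
                                           class = "projection_set"), 1),
               "invalid-mean")
})

test_that("aperture sampling density barely changes total counts", {
  grid <- volume_template(8, 0.5)
  src <- make_point_sources(matrix(c(0.25, 0.25, 0.25), 1), 1, grid)
  totals <- vapply(c(1, 13), function(n) {
    sum(forward_project(src, tiny_model(aperture_samples = n),
                        exposure = 1)$frames)
  }, numeric(1))
  expect_lt(abs(totals[2] - totals[1]) / totals[1], 0.02)
})

test_that("rotating the volume equals relabelling the angles", {
  m <- tiny_model(aperture_samples = 3, n_projections = 8)
  grid <- volume_template(c(8, 8, 4), 0.25)
  ph <- make_capillary(capillary_spec(inner_diameter = 0.8, length = 3),
                       grid)
  step <- 360 / 8
  y <- forward_project(ph, m, exposure = 1)
  rot <- pinspect:::rotate_volume(ph, step)
  y_rot <- forward_project(rot, m, exposure = 1)
  # frame k of the rotated volume matches frame k+1 of the original
  for (k in 1:7)
    expect_lt(rel_rms(y$frames[, , k + 1], y_rot$frames[, , k]), 0.05)
})

test_that("geometry mismatches and oversize targets are refused", {
  m <- tiny_model()
  grid <- tiny_grid()
  y <- forward_project(random_volume(grid), m, exposure = 1)
  m2 <- tiny_model(b = 11)
  expect_error(back_project(y, m2, grid), "geometry error")
  big <- volume_template(40, 2)
  big$values[] <- 1
  expect_error(forward_project(big, m, exposure = 1), "target-too-large")
})
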