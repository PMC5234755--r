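make_plane <- function(values, pixel = 1) {
  structure(list(values = values, pixel_size = rep(pixel, 2),
                 origin = -dim(values) * pixel / 2),
            class = "plane_image")
}

test_that("line profiles sample bilinearly and respect orientation", {
  img <- make_plane(matrix(3, 20, 20))
  pr <- line_profile(img, c(-8, 0), c(8, 0), 50)
  expect_true(all(abs(pr$values - 3) < 1e-12))
  # bilinear interpolation is exact on a linear ramp
  xs <- (1:20 - 0.5) - 10
  ramp <- make_plane(outer(xs, rep(1, 20)))
  pr2 <- line_profile(ramp, c(-8, 0), c(8, 0), 33)
  expect_equal(pr2$values, seq(-8, 8, length.out = 33), tolerance = 1e-12)
  # reversing the endpoints reverses the samples
  pr3 <- line_profile(ramp, c(8, 0), c(-8, 0), 33)
  expect_equal(pr3$values, rev(pr2$values), tolerance = 1e-12)
  expect_error(line_profile(img, c(-30, 0), c(0, 0), 10), "out-of-bounds")
})

test_that("fwhm recovers widths of known profiles", {
  # Gaussian: FWHM = 2 sqrt(2 ln 2) sigma
  x <- seq(-8, 8, by = 0.05)
  g <- exp(-x^2 / 2)
  expect_equal(fwhm(g, 0.05), 2.3548, tolerance = 0.01 / 2.3548)
  # rectangular pulse of width w: half-maximum crossings at the edges
  for (w in c(2, 3.6)) {
    r <- as.numeric(abs(x) <= w / 2)
    expect_lt(abs(fwhm(r, 0.05) - w), 0.05 + 1e-12)
  }
  # monotone ramp has no interior peak
  expect_error(fwhm(seq(0, 1, length.out = 100), 0.1), "no-peak")
})

test_that("peak-valley contrast matches the two-Gaussian oracle", {
  # oracle: superposition of two unit Gaussians at distance s = 2 FWHM;
  # valley = 2 exp(-(s/2)^2 / (2 sigma^2)) = 0.12500, peak ~= 1.0000152,
  # hence ratio 0.1250 (computed independently from the closed form)
  sigma <- 1
  s <- 2 * 2.3548 * sigma
  x <- seq(-6, s + 6, by = 0.01)
  prof <- list(values = exp(-x^2 / 2) + exp(-(x - s)^2 / 2),
               spacing = 0.01, positions = x - x[1])
  ctr <- c(0, s) - x[1]
  expect_equal(peak_valley_contrast(prof, ctr, s), 0.125, tolerance = 0.005)
  # fully separated features
  sep <- list(values = c(0, 1, 0, 0, 0, 1, 0), spacing = 1, positions = 0:6)
  expect_equal(peak_valley_contrast(sep, c(1, 5), 4), 0)
  # flat profile is unresolvable
  flat <- list(values = rep(2, 50), spacing = 1, positions = 0:49)
  expect_equal(peak_valley_contrast(flat, c(10, 30), 20), 1)
  # fewer than two locatable features
  expect_equal(peak_valley_contrast(sep, 1, 4), 1)
})

test_that("ground-truth phantoms score as fully resolved", {
  grid <- volume_template(c(32, 32, 4), 0.125)
  ph <- make_jaszczak(jaszczak_spec(cylinder_height = 4), grid)
  rep <- limiting_resolution(ph, attr(ph, "descriptor"))
  expect_true(all(rep$resolved))
  expect_equal(rep$limiting_resolution, 0.5)
})

test_that("heavy blur removes all resolved sectors", {
  grid <- volume_template(c(32, 32, 4), 0.25)
  ph <- make_jaszczak(jaszczak_spec(cylinder_height = 4), grid)
  # 5 mm FWHM = 20 voxels: swamps even the 2 mm sector (4 mm pitch)
  blurred <- gaussian_smooth(ph, 5 / 0.25)
  rep <- limiting_resolution(blurred, attr(ph, "descriptor"))
  expect_false(any(rep$resolved))
  expect_true(is.na(rep$limiting_resolution))
})

test_that("contrast degrades monotonically with blur", {
  grid <- volume_template(c(32, 32, 4), 0.25)
  ph <- make_jaszczak(jaszczak_spec(cylinder_height = 4), grid)
  desc <- attr(ph, "descriptor")
  blur_mm <- c(0.2, 0.5, 1, 2, 3.5, 5)
  c15 <- vapply(blur_mm, function(bmm) {
    sm <- gaussian_smooth(ph, bmm / 0.25)
    rep <- limiting_resolution(sm, desc)
    unname(rep$per_feature_contrast[format(1.5)])
  }, numeric(1))
  # allow tiny jitter once the contrast saturates near 1
  expect_true(all(diff(c15) >= -0.02))
  # blurred versions never resolve more than the truth
  rep0 <- limiting_resolution(ph, desc)
  rep5 <- limiting_resolution(gaussian_smooth(ph, 5 / 0.25), desc)
  expect_true(is.na(rep5$limiting_resolution) ||
                rep5$limiting_resolution >= rep0$limiting_resolution)
})

test_that("the resolution report ignores global intensity scaling", {
  grid <- volume_template(c(32, 32, 4), 0.25)
  ph <- make_jaszczak(jaszczak_spec(cylinder_height = 4), grid)
  sm <- gaussian_smooth(ph, 4)
  desc <- attr(ph, "descriptor")
  r1 <- limiting_resolution(sm, desc)
  sm$values <- sm$values * 1000
  r2 <- limiting_resolution(sm, desc)
  expect_equal(r1$per_feature_contrast, r2$per_feature_contrast,
               tolerance = 1e-12)
  expect_identical(r1$resolved, r2$resolved)
})
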