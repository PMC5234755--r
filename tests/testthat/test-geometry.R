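test_that("magnification is the detector/target distance ratio", {
  expect_equal(magnification(acquisition_geometry(36, 252)), 7.0)
  expect_equal(magnification(acquisition_geometry(28, 252)), 9.0)
  expect_equal(magnification(acquisition_geometry(45.8, 252)), 5.5,
               tolerance = 1e-3)
  expect_error(acquisition_geometry(0, 100), "invalid-geometry")
  expect_error(acquisition_geometry(10, -1), "invalid-geometry")
})

test_that("magnification is monotone in both distances", {
  bs <- seq(10, 60, by = 5)
  ms_b <- vapply(bs, function(b) magnification(acquisition_geometry(b, 252)),
                 numeric(1))
  expect_true(all(diff(ms_b) < 0))
  fs <- seq(100, 400, by = 25)
  ms_f <- vapply(fs, function(f) magnification(acquisition_geometry(36, f)),
                 numeric(1))
  expect_true(all(diff(ms_f) > 0))
})

test_that("effective pinhole diameter follows the penetration closed form", {
  # opaque limit: d_eff -> d
  opaque <- collimator_spec(0.5, "lead", mu = 1e12)
  expect_equal(effective_pinhole_diameter(opaque), 0.5, tolerance = 1e-9)
  # hand-evaluated values of sqrt(d (d + (2/mu) tan(alpha/2)))
  expect_equal(effective_pinhole_diameter(
    collimator_spec(0.5, "tungsten", mu = 3.6, acceptance_full_angle = 60)),
    0.6406, tolerance = 1e-4)
  expect_equal(effective_pinhole_diameter(
    collimator_spec(1.5, "lead", mu = 2.7, acceptance_full_angle = 60)),
    1.7005, tolerance = 1e-4)
  expect_error(collimator_spec(0.5, "lead", mu = -1), "invalid-material")
})

test_that("effective diameter always exceeds the physical bore", {
  for (d in c(0.3, 0.5, 1.0, 1.5, 2.0))
    for (mu in c(0.5, 1, 2.7, 3.6, 10))
      expect_gte(effective_pinhole_diameter(
        collimator_spec(d, "lead", mu = mu)), d)
})

test_that("predicted system resolution combines intrinsic and aperture terms", {
  mk <- function(M, d_eff, r_int = 3.9) {
    # opaque collimator with bore = d_eff gives exactly that effective size
    system_model(detector_spec(540, 400, pixel_pitch = 2,
                               intrinsic_fwhm = r_int),
                 collimator_spec(d_eff, "tungsten", mu = 1e12),
                 acquisition_geometry(252 / M, 252))
  }
  expect_equal(predicted_system_resolution(mk(9, 0.5)), 0.705,
               tolerance = 1e-3)
  expect_equal(predicted_system_resolution(mk(7, 1.5)), 1.803,
               tolerance = 1e-3)
  # both terms vanish: huge magnification, zero aperture
  expect_lt(predicted_system_resolution(mk(1e6, 0)), 1e-4)
  # monotone improvement with magnification at fixed small aperture
  res <- vapply(2:12, function(M)
    predicted_system_resolution(mk(M, 0.5)), numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("maximum target size is the demagnified detector minimum", {
  mk <- function(M) system_model(detector_spec(540, 400, pixel_pitch = 2),
                                 collimator_spec(1, "lead"),
                                 acquisition_geometry(252 / M, 252))
  expect_equal(max_target_diameter(mk(1)), 400)
  expect_equal(max_target_diameter(mk(9)), 44.4, tolerance = 1e-2)
  expect_equal(max_target_diameter(mk(7)), 57.1, tolerance = 1e-2)
})

test_that("central-ray point projection inverts and magnifies", {
  m7 <- system_model(detector_spec(540, 400, pixel_pitch = 2),
                     collimator_spec(1, "lead"),
                     acquisition_geometry(36, 252))
  m9 <- system_model(detector_spec(540, 400, pixel_pitch = 2),
                     collimator_spec(1, "lead"),
                     acquisition_geometry(28, 252))
  expect_equal(project_point(m7, c(0, 0, 0), 17), c(0, 0))
  expect_equal(project_point(m7, c(1, 0, 0), 0), c(-7, 0))
  expect_equal(project_point(m9, c(2, 0, 0), 180), c(18, 0),
               tolerance = 1e-9)
  expect_error(project_point(m7, c(40, 0, 0), 0), "out-of-field")
})

test_that("point projection is 360-degree periodic", {
  m <- system_model(detector_spec(540, 400, pixel_pitch = 2),
                    collimator_spec(1, "lead"),
                    acquisition_geometry(36, 252))
  for (th in c(0, 33.3, 90, 201.7)) {
    p <- c(1.3, -0.7, 2.1)
    expect_equal(project_point(m, p, th), project_point(m, p, th + 360),
                 tolerance = 1e-9)
  }
})

test_that("aperture sampling has zero centroid and disc second moment", {
  for (n in c(2, 3, 7, 12, 13, 37)) {
    m <- tiny_model(aperture_samples = n)
    pts <- pinspect:::aperture_sample_points(m)
    r_disc <- effective_pinhole_diameter(m$collimator) / 2
    expect_equal(colMeans(pts), c(0, 0), tolerance = 1e-12)
    expect_equal(mean(pts[, 1]^2 + pts[, 2]^2), r_disc^2 / 2,
                 tolerance = 1e-10)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(detector_spec(0, 400), "invalid-geometry")
  expect_error(detector_spec(540, 400, pixel_pitch = 300), "invalid-geometry")
  expect_error(collimator_spec(-1, "lead"), "invalid-geometry")
  expect_error(collimator_spec(1, "lead", acceptance_full_angle = 190),
               "invalid-geometry")
  expect_error(acquisition_geometry(10, 30, 4, angles = c(0, 10, 5, 20)),
               "invalid-geometry")
  expect_error(acquisition_geometry(10, 30, 4, angles = c(0, 100, 200, 400)),
               "invalid-geometry")
})
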