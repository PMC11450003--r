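test_that("resolution limit follows 0.8 c / f_c and the printed values", {
  expect_equal(resolution_limit(1020, 3.5e6), 233e-6, tolerance = 0.01)
  expect_equal(resolution_limit(1020, 5e6, factor = 1), 204e-6, tolerance = 0.01)
  expect_equal(resolution_limit(2040, 3.5e6), 2 * resolution_limit(1020, 3.5e6))
})

test_that("scan_dataset validates geometry and warns on aliasing pitch", {
  tt <- seq(0, 5e-6, by = 1 / 65e6)
  pos <- seq(-1e-3, 1e-3, by = 125e-6)
  ds <- scan_dataset(pos, tt, matrix(0, length(tt), length(pos)))
  expect_equal(ds$pitch, 125e-6)
  expect_warning(
    scan_dataset(seq(0, 2e-3, by = 250e-6), tt,
                 matrix(0, length(tt), 9), cutoff = 5e6),
    "aliasing")
  expect_error(scan_dataset(c(0, 1e-3, 1.5e-3), tt, matrix(0, length(tt), 3)),
               "equispaced")
})

test_that("zero traces reconstruct to a zero image; envelope image is nonnegative", {
  tt <- seq(0, 8e-6, by = 1 / 65e6)
  pos <- seq(-1.5e-3, 1.5e-3, by = 250e-6)
  suppressWarnings(
    ds <- scan_dataset(pos, tt, matrix(0, length(tt), length(pos))))
  med <- coarse_medium(depth = 8e-3, soft_bottom = FALSE)
  img0 <- reconstruct(ds, med)
  expect_true(all(img0$values == 0))
  expect_identical(nrow(localize(img0)), 0L)
  set.seed(12)
  suppressWarnings(
    dsr <- scan_dataset(pos, tt,
                        matrix(rnorm(length(tt) * length(pos)),
                               length(tt))))
  imgr <- reconstruct(dsr, med)
  expect_true(all(imgr$values >= 0))
})

test_that("localize finds a known Gaussian blob center and respects suppression", {
  med <- coarse_medium()
  v <- exp(-(outer((med$z - 4e-3)^2, (med$x - 1e-3)^2, `+`)) / (2 * (0.4e-3)^2))
  img <- structure(list(x = med$x, z = med$z, values = v, dx = med$dx,
                        c0 = 1020, envelope_mode = TRUE, thickness = 8e-3),
                   class = "pa_image")
  pk <- localize(img, n_peaks = 1, smooth_radius = 0)
  expect_lt(abs(pk$z[1] - 4e-3), med$dx + 1e-12)
  expect_lt(abs(pk$x[1] - 1e-3), med$dx + 1e-12)
  # two blobs: suppression removes the twin within the radius
  v2 <- v + 0.8 * exp(-(outer((med$z - 4e-3)^2, (med$x + 1.5e-3)^2, `+`)) /
                        (2 * (0.4e-3)^2))
  img$values <- v2
  pk2 <- localize(img, n_peaks = 2, smooth_radius = 0,
                  suppression_radius = 1e-3)
  expect_equal(pk2$x, c(1e-3, -1.5e-3), tolerance = 1e-4)
})

test_that("single-channel dataset localizes to the channel and its backside mirror", {
  ph <- phantom_spec(thickness = 9e-3,
                     channels = list(list(depth = 5e-3, offset = 0,
                                          diameter = 1.5e-3)))
  med <- build_medium(ph, dx = 50e-6, width = 11e-3, f_max = 2e6,
                      sponge_cells = 30L, homogeneous = TRUE)
  p0 <- initial_pressure_from_absorption(ph, med)
  sx <- seq(-4e-3, 4e-3, by = 250e-6)
  rec <- simulate_forward(med, p0, 18e-6, sensor_x = sx)
  suppressWarnings(
    ds <- scan_dataset(sx, rec$time, velocity_to_pressure(rec$u), truth = ph))
  medr <- build_medium(NULL, dx = 50e-6, width = 11e-3, depth = 16e-3,
                       thickness = 9e-3, f_max = 2e6, sponge_cells = 30L,
                       soft_bottom = FALSE)
  img <- reconstruct(ds, medr)
  pk <- localize(img, n_peaks = 2, suppression_radius = 2.5e-3,
                 smooth_radius = 0.75e-3)
  expect_lt(abs(pk$z[1] - 5e-3), 250e-6)
  expect_lt(abs(pk$x[1] - 0), 250e-6)
  # mirror artifact at depth mirrored about the 9 mm backside: 13 mm
  expect_lt(abs(pk$z[2] - 13e-3), 400e-6)
  expect_gt(pk$amplitude[1], pk$amplitude[2])
})

test_that("halved aperture still localizes within twice the resolution limit", {
  ph <- phantom_spec(thickness = 9e-3,
                     channels = list(list(depth = 5e-3, offset = 0,
                                          diameter = 1.5e-3)))
  med <- build_medium(ph, dx = 50e-6, width = 11e-3, f_max = 2e6,
                      sponge_cells = 30L, homogeneous = TRUE)
  p0 <- initial_pressure_from_absorption(ph, med)
  sx <- seq(-4e-3, 4e-3, by = 500e-6)     # sparse scan
  rec <- simulate_forward(med, p0, 14e-6, sensor_x = sx)
  suppressWarnings(
    ds <- scan_dataset(sx, rec$time, velocity_to_pressure(rec$u)))
  medr <- build_medium(NULL, dx = 50e-6, width = 11e-3, depth = 9e-3,
                       thickness = 9e-3, f_max = 2e6, sponge_cells = 30L,
                       soft_bottom = FALSE)
  img <- reconstruct(ds, medr)
  pk <- localize(img, n_peaks = 1, smooth_radius = 0.75e-3)
  lim <- 2 * resolution_limit(1020, 3.5e6)
  expect_lt(sqrt((pk$z[1] - 5e-3)^2 + pk$x[1]^2), lim)
})
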