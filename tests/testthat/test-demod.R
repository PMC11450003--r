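test_that("direct least-squares ellipse fit recovers generated parameters", {
  pts <- ellipse_points(0.1, -0.05, 1.2, 0.8, 30 * pi / 180)
  e <- fit_ellipse(pts$x, pts$y)
  expect_equal(e$center, c(0.1, -0.05), tolerance = 1e-6)
  expect_equal(c(e$a, e$b), c(1.2, 0.8), tolerance = 1e-6)
  expect_equal(e$phi, 30 * pi / 180, tolerance = 1e-6)
  expect_lt(e$residual, 1e-9)
  # unit circle
  th <- seq(0, 2 * pi, length.out = 200)
  e0 <- fit_ellipse(cos(th), sin(th))
  expect_equal(e0$center, c(0, 0), tolerance = 1e-9)
  expect_equal(c(e0$a, e0$b), c(1, 1), tolerance = 1e-9)
})

test_that("noisy ellipse samples are recovered to Monte-Carlo tolerance", {
  set.seed(3)
  errs <- replicate(20, {
    pts <- ellipse_points(0.1, -0.05, 1.2, 0.8, 30 * pi / 180, noise = 0.01)
    e <- fit_ellipse(pts$x, pts$y)
    max(abs(c(e$center - c(0.1, -0.05), e$a - 1.2, e$b - 0.8,
              e$phi - 30 * pi / 180)))
  })
  expect_lt(median(errs), 1e-2)
})

test_that("degenerate inputs produce a fit error", {
  expect_error(fit_ellipse(1:20, 2 * (1:20)), "collinear|ellipse")
  expect_error(fit_ellipse(1:4, c(1, 2, 1, 2)), "at least 6")
})

test_that("ellipse correction projects on-ellipse points onto the unit circle", {
  pts <- ellipse_points(0.3, -0.2, 1.5, 0.6, -20 * pi / 180)
  e <- fit_ellipse(pts$x, pts$y)
  cc <- correct_iq(pts$x, pts$y, e)
  expect_true(all(abs(sqrt(cc$i^2 + cc$q^2) - 1) <= 1e-9))
  # identity ellipse (circle) leaves points unchanged
  th <- seq(0, 2 * pi, length.out = 100)
  ec <- fit_ellipse(cos(th), sin(th))
  cc2 <- correct_iq(cos(th), sin(th), ec)
  expect_equal(cc2$i, cos(th), tolerance = 1e-8)
  expect_equal(cc2$q, sin(th), tolerance = 1e-8)
})

test_that("phase demodulation unwraps multi-turn ramps without jumps", {
  ramp <- seq(0, 6 * pi, length.out = 2000)
  th <- demodulate_phase(cos(ramp), sin(ramp))
  expect_equal(as.vector(th), ramp, tolerance = 1e-9)
  # constant point
  thc <- demodulate_phase(rep(cos(pi / 4), 50), rep(sin(pi / 4), 50))
  expect_equal(as.vector(thc), rep(pi / 4, 50))
  # random-walk phase crossing +-pi: no 2 pi steps after unwrap
  set.seed(1)
  w <- cumsum(rnorm(5000, sd = 0.5))
  thw <- demodulate_phase(cos(w), sin(w))
  expect_lt(max(abs(diff(thw))), pi)
})

test_that("signal dropouts are interpolated and counted", {
  ramp <- seq(0, 4 * pi, length.out = 500)
  i <- cos(ramp); q <- sin(ramp)
  bad <- 200:205
  i[bad] <- 1e-4; q[bad] <- 1e-4
  th <- demodulate_phase(i, q, dropout = 0.05)
  expect_identical(attr(th, "dropouts"), length(bad))
  expect_equal(as.vector(th), ramp, tolerance = 0.05)
})

test_that("phase-to-displacement follows the quarter-wavelength rule", {
  expect_equal(phase_to_displacement(c(0, 4 * pi)), c(0, 1550e-9))
  expect_equal(phase_to_displacement(c(0, pi))[2], 387.5e-9)
  expect_equal(phase_to_displacement(c(2, 2)), c(0, 0))
})

test_that("differentiation recovers sinusoid amplitude and attenuates above cutoff", {
  fs <- 65e6
  t <- seq(0, 40e-6, by = 1 / fs)
  d1 <- 1e-9 * sin(2 * pi * 1e6 * t)
  u1 <- displacement_to_velocity(d1, fs, cutoff = 5e6)
  mid <- seq(200, length(t) - 200)
  expect_equal(max(abs(u1[mid])), 2 * pi * 1e6 * 1e-9, tolerance = 0.01)
  expect_true(all(displacement_to_velocity(rep(1e-9, 1000), fs) < 1e-12))
  d10 <- 1e-9 * sin(2 * pi * 10e6 * t)
  u10 <- displacement_to_velocity(d10, fs, cutoff = 5e6)
  atten <- max(abs(u10[mid])) / (2 * pi * 10e6 * 1e-9)
  expect_lt(20 * log10(atten), -20)
})

test_that("velocity converts to pressure by half the impedance", {
  expect_equal(velocity_to_pressure(4e-3, 1.02e6), 2040)  # ~2 kPa
  expect_equal(velocity_to_pressure(0), 0)
  u <- rnorm(10)
  expect_equal(velocity_to_pressure(2 * u), 2 * velocity_to_pressure(u))
})

test_that("segment averaging is the identity for N = 1 and gains sqrt(N) in SNR", {
  x <- rnorm(100)
  expect_identical(average_segments(matrix(x, ncol = 1)), x)
  set.seed(8)
  sig <- sin(2 * pi * (1:2000) / 50)
  N <- 100
  noisy <- matrix(sig, 2000, N) + matrix(rnorm(2000 * N), 2000)
  avg <- average_segments(noisy)
  resid_1 <- sqrt(mean((noisy[, 1] - sig)^2))
  resid_N <- sqrt(mean((avg - sig)^2))
  expect_equal(resid_1 / resid_N, sqrt(N), tolerance = 0.15)
})

test_that("Hilbert envelope is flat for a tone, zero for zero, nonnegative always", {
  t <- seq(0, 1e-4, by = 1 / 65e6)
  x <- 0.7 * sin(2 * pi * 1e6 * t)
  env <- envelope(x)
  mid <- seq(300, length(x) - 300)
  expect_true(all(abs(env[mid] - 0.7) < 0.02 * 0.7))
  expect_true(all(envelope(rep(0, 64)) == 0))
  set.seed(2)
  expect_true(all(envelope(rnorm(512)) >= 0))
})

test_that("full demodulation chain inverts synthesis under strong distortion", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  d_true <- gauss_burst(t, 15e-6, 1.5e-6, 2e6, amp = 5e-9)
  cfg <- demod_config(fs = fs)
  # distortions up to gain ratio 1.5, offsets 0.3 radius, quadrature 10 deg
  for (m in list(iq_model(g_i = 1.2, g_q = 1, o_i = 0.1, o_q = 0.1,
                          quad_error = 5 * pi / 180),
                 iq_model(g_i = 1.5, g_q = 1, o_i = 0.3, o_q = -0.3,
                          quad_error = 10 * pi / 180))) {
    rec <- synthesize_iq(d_true, m, fs = fs, trigger_artifact = FALSE)
    res <- demodulate_record(rec, cfg, ellipse = reference_ellipse(m, fs))
    expect_lt(sqrt(mean((res$d - d_true)^2)), 1e-9)
  }
})

test_that("pressure equals the filtered derivative chain computed in one expression", {
  fs <- 65e6
  t <- seq(0, 25e-6, by = 1 / fs)
  d_true <- gauss_burst(t, 12e-6, 1e-6, 2.5e6, amp = 4e-9)
  m <- iq_model()
  rec <- synthesize_iq(d_true, m, fs = fs, trigger_artifact = FALSE)
  res <- demodulate_record(rec, demod_config(fs = fs),
                           ellipse = reference_ellipse(m, fs))
  # independent single-expression reference: p = Z/2 * LP(central diff d)
  n <- length(d_true)
  du <- c(d_true[2] - d_true[1],
          (d_true[3:n] - d_true[1:(n - 2)]) / 2,
          d_true[n] - d_true[n - 1]) * fs
  p_ref <- 1.02e6 / 2 * lowpass_zero_phase(du, fs, 5e6, 4)
  expect_lt(sqrt(mean((res$p - p_ref)^2)), 1e-6 * max(abs(p_ref)))
})

test_that("demodulation is invariant to a global static phase rotation", {
  fs <- 65e6
  t <- seq(0, 20e-6, by = 1 / fs)
  d_true <- gauss_burst(t, 10e-6, 1e-6, 2e6, amp = 3e-9)
  res <- lapply(c(0, 1.1), function(th1) {
    m <- iq_model(theta1 = th1)
    rec <- synthesize_iq(d_true, m, fs = fs, trigger_artifact = FALSE)
    demodulate_record(rec, demod_config(fs = fs),
                      ellipse = reference_ellipse(m, fs))
  })
  expect_equal(res[[1]]$d, res[[2]]$d, tolerance = 1e-12)
})
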