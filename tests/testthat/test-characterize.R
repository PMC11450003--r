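test_that("Welch PSD of white noise is flat at 2 sigma^2 / fs and Parseval-consistent", {
  set.seed(4)
  fs <- 10e6; sg <- 0.7
  x <- rnorm(2^17, sd = sg)
  spec <- nev_spectrum(x, fs, nperseg = 4096)
  expect_true(all(spec$psd >= 0))
  expect_equal(mean(spec$psd), 2 * sg^2 / fs, tolerance = 0.10)
  df <- diff(spec$freq[1:2])
  expect_equal(sum(spec$psd) * df, var(x), tolerance = 0.05)
  expect_equal(spec$nev_density, sqrt(spec$psd))
})

test_that("a pure tone concentrates in its bin; zero trace gives zero spectrum", {
  fs <- 10e6
  t <- (0:(2^15 - 1)) / fs
  spec <- nev_spectrum(sin(2 * pi * 1e6 * t), fs, nperseg = 4096)
  expect_equal(spec$freq[which.max(spec$psd)], 1e6, tolerance = 0.01)
  z <- nev_spectrum(rep(0, 2^15), fs, nperseg = 4096)
  expect_true(all(z$psd == 0))
  expect_error(nev_spectrum(rnorm(100), fs, nperseg = 4096), "shorter")
})

test_that("band-integrated NEV matches the trace RMS; NEP follows Z/2 scaling", {
  set.seed(5)
  fs <- 10e6; sg <- 4e-3
  spec <- nev_spectrum(rnorm(2^17, sd = sg), fs, nperseg = 4096)
  res <- integrate_nev(spec, band = c(0, fs / 2), impedance = 1.02e6)
  expect_equal(res$nev, sg, tolerance = 0.10)
  expect_equal(res$nep / res$nev, 1.02e6 / 2)
  # NEV of 4 mm/s corresponds to ~2 kPa on PDMS
  expect_equal(1.02e6 / 2 * 4e-3, 2040)
  zero <- spec; zero$psd[] <- 0
  expect_equal(integrate_nev(zero)$nev, 0)
})

test_that("sensitivity spectrum is the ratio of magnitude spectra with masking", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  p <- exp(-((t - 8e-6) / 0.08e-6)^2)         # broadband reference pulse
  s_eq <- sensitivity_spectrum(p, p, fs)
  expect_true(all(abs(s_eq$S[s_eq$valid] - 1) < 1e-9))
  s_half <- sensitivity_spectrum(0.5 * p, p, fs)
  expect_true(all(abs(s_half$S[s_half$valid] - 0.5) < 1e-9))
  expect_error(sensitivity_spectrum(p, 0 * p, fs), "zero")
})

test_that("sensitivity recovers a 2nd-order low-pass response and its 3 dB point", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  p <- exp(-((t - 8e-6) / 0.08e-6)^2)
  bf <- signal::butter(2, 3.5e6 / (fs / 2), "low")
  cand <- as.numeric(signal::filter(bf, p))
  ss <- sensitivity_spectrum(cand, p, fs)
  fr <- signal::freqz(bf, n = 2048, Fs = fs)
  href <- approx(fr$f, Mod(fr$h), xout = ss$freq)$y
  sel <- ss$valid & ss$freq > 0 & ss$freq < 10e6
  expect_true(all(abs(ss$S[sel] - href[sel]) / href[sel] < 0.05))
  expect_equal(bandwidth_3db(ss), 3.5e6, tolerance = 0.05)
  # scale equivariance of the cutoff
  cand2 <- as.numeric(signal::filter(signal::butter(2, 7e6 / (fs / 2), "low"), p))
  bw2 <- bandwidth_3db(sensitivity_spectrum(cand2, p, fs))
  expect_equal(bw2 / bandwidth_3db(ss), 2, tolerance = 0.05)
})

test_that("flat sensitivity returns the band edge with a flag", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  p <- exp(-((t - 8e-6) / 0.08e-6)^2)
  s <- sensitivity_spectrum(p, p, fs)
  bw <- bandwidth_3db(s)
  expect_identical(attr(bw, "flag"), "no-crossing")
  expect_equal(as.numeric(bw), max(s$freq[s$valid]))
})

test_that("SNR is envelope peak over noise RMS and doubles with amplitude", {
  fs <- 65e6
  t <- seq(0, 40e-6, by = 1 / fs)
  set.seed(6)
  noise <- rnorm(length(t), sd = 0.01)
  pulse <- gauss_burst(t, 25e-6, 2e-6, 2e6, amp = 0.3)
  s1 <- snr(pulse + noise, fs, c(1e-6, 10e-6))
  expect_equal(s1, 0.3 / 0.01, tolerance = 0.10)
  s2 <- snr(2 * pulse + noise, fs, c(1e-6, 10e-6))
  expect_equal(s2 / s1, 2, tolerance = 0.10)
  expect_error(snr(c(rep(0, 200), rep(1, 100)), fs, c(0, 150 / fs)),
               "zero RMS")
  # noise-only traces: envelope max over RMS stays near the Rayleigh
  # extreme-value level sqrt(2 log n), far from a genuine pulse SNR
  n <- 4000
  s_noise <- replicate(20, snr(rnorm(n), fs, c(1e-6, 20e-6)))
  lvl <- sqrt(2 * log(n))
  expect_true(all(s_noise > 0.5 * lvl & s_noise < 2 * lvl))
})

test_that("measured SNR improves as sqrt(N) under segment averaging", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  d_true <- gauss_burst(t, 15e-6, 1e-6, 2.5e6, amp = 20e-9)
  m <- iq_model(sigma = 0.03)
  ell <- reference_ellipse(m, fs)
  cfg <- demod_config(fs = fs)
  get_snr <- function(N, seed) {
    rec <- synthesize_iq(d_true, m, fs = fs, n_segments = N, seed = seed,
                         trigger_artifact = FALSE)
    r <- demodulate_record(rec, cfg, ellipse = ell)
    snr(r$u, fs, c(1e-6, 10e-6), signal_window = c(12e-6, 18e-6))
  }
  s1 <- mean(vapply(1:10, function(k) get_snr(1, k), numeric(1)))
  s16 <- mean(vapply(1:4, function(k) get_snr(16, 100 + k), numeric(1)))
  expect_equal(s16 / s1, 4, tolerance = 0.15)
})

test_that("SNR grows monotonically with ink concentration at fixed noise", {
  fs <- 65e6
  t <- seq(0, 30e-6, by = 1 / fs)
  d_base <- gauss_burst(t, 15e-6, 1e-6, 2.5e6, amp = 4e-9)
  m <- iq_model(sigma = 0.03)
  ell <- reference_ellipse(m, fs)
  cfg <- demod_config(fs = fs)
  snrs <- vapply(c(0.1, 0.3, 1), function(conc) {
    rec <- synthesize_iq(conc * d_base, m, fs = fs, n_segments = 50, seed = 5)
    r <- demodulate_record(rec, cfg, ellipse = ell)
    snr(r$u, fs, c(1e-6, 10e-6), signal_window = c(12e-6, 18e-6))
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("excitation bookkeeping: 500 W x 400 ns at 1 kHz", {
  ex <- excitation_summary(500, 400e-9, 1e3)
  expect_equal(ex$energy, 200e-6)
  expect_equal(ex$avg_power, 0.2)
})
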