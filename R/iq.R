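# synthesis of homodyne LDV I/Q photodetector signals from surface motion

#' Homodyne I/Q detection model
#'
#' Parameters of the interferometric readout. The reference and
#' measurement fields r exp(i theta0) and m exp(i (theta1 + theta(t)))
#' combine in a 90-degree optical hybrid; the balanced photocurrent pairs
#' give I = 2 mu |r m| cos(theta'), Q = 2 mu |r m| sin(theta') with
#' theta'(t) = theta(t) + theta1 - theta0. Hardware imperfections enter as
#' per-channel gains, DC offsets, a quadrature error and additive noise,
#' turning the ideal circular I/Q locus into a shifted, tilted ellipse.
#'
#' @param r,m Reference and measurement field amplitudes (> 0).
#' @param mu Photodiode responsivity (signal gain); the undistorted locus
#'   radius is `2 * mu * r * m`.
#' @param theta0,theta1 Static phases of the two arms, rad.
#' @param g_i,g_q Electronic gains of the I and Q channels.
#' @param o_i,o_q DC offsets added to I and Q.
#' @param quad_error Quadrature phase error epsilon, rad: Q uses
#'   sin(theta' + epsilon).
#' @param sigma Additive white noise standard deviation per sample (same
#'   units as I/Q).
#' @param lambda Probe wavelength, m (1550 nm).
#' @return An `iq_model` list; `radius` holds `2 mu r m`.
#' @export
iq_model <- function(r = 1, m = 1, mu = 0.5, theta0 = 0, theta1 = 0,
                     g_i = 1, g_q = 1, o_i = 0, o_q = 0,
                     quad_error = 0, sigma = 0, lambda = 1550e-9) {
  stopifnot(r > 0, m > 0, mu > 0, lambda > 0, sigma >= 0)
  structure(list(r = r, m = m, mu = mu, theta0 = theta0, theta1 = theta1,
                 g_i = g_i, g_q = g_q, o_i = o_i, o_q = o_q,
                 quad_error = quad_error, sigma = sigma, lambda = lambda,
                 radius = 2 * mu * abs(r * m)),
            class = "iq_model")
}

#' Synthesize a triggered I/Q record from a displacement trace
#'
#' Maps surface displacement to double-pass interferometric phase,
#' theta'(t) = 4 pi d(t) / lambda + (theta1 - theta0), and renders the
#' distorted photodetector outputs
#' I = g_i R cos(theta') + o_i, Q = g_q R sin(theta' + eps) + o_q with
#' R = 2 mu |r m|, plus independent white noise per segment. All segments
#' share the same deterministic signal (triggered acquisition at the pulse
#' repetition rate); an optional short transient at the segment start
#' mimics the electromagnetic interference of the excitation pulse firing
#' at t = 0.
#'
#' @param displacement Displacement trace in m, sampled at `fs`.
#' @param model An [iq_model()].
#' @param fs Sampling rate, Hz (65 MS/s default).
#' @param n_segments Number of triggered segments.
#' @param seed Optional integer seed for the per-segment noise.
#' @param rep_rate Trigger repetition rate, Hz (sets trigger times).
#' @param trigger_artifact Add the t = 0 interference transient.
#' @param artifact_amplitude Amplitude of that transient relative to the
#'   locus radius.
#' @return An `iq_record`: samples x segments matrices `i` and `q`, `fs`,
#'   `trigger_times`, the model and seed.
#' @export
synthesize_iq <- function(displacement, model = iq_model(), fs = 65e6,
                          n_segments = 1, seed = NULL, rep_rate = 1e3,
                          trigger_artifact = TRUE,
                          artifact_amplitude = 0.3) {
  stopifnot(inherits(model, "iq_model"))
  if (length(displacement) == 0) stop("empty displacement trace")
  if (!is.null(seed)) set.seed(seed)
  n <- length(displacement)
  theta <- 4 * pi * displacement / model$lambda + (model$theta1 - model$theta0)
  R <- model$radius
  i_sig <- model$g_i * R * cos(theta) + model$o_i
  q_sig <- model$g_q * R * sin(theta + model$quad_error) + model$o_q
  if (trigger_artifact && artifact_amplitude > 0) {
    # damped ring-down over ~0.3 us right after the trigger
    t <- (seq_len(n) - 1) / fs
    art <- artifact_amplitude * R * exp(-t / 1e-7) * cos(2 * pi * 20e6 * t)
    i_sig <- i_sig + art
    q_sig <- q_sig + art
  }
  I <- matrix(i_sig, n, n_segments)
  Q <- matrix(q_sig, n, n_segments)
  if (model$sigma > 0) {
    I <- I + matrix(rnorm(n * n_segments, sd = model$sigma), n)
    Q <- Q + matrix(rnorm(n * n_segments, sd = model$sigma), n)
  }
  structure(list(i = I, q = Q, fs = fs,
                 trigger_times = (seq_len(n_segments) - 1) / rep_rate,
                 model = model, seed = seed),
            class = "iq_record")
}

#' @export
print.iq_record <- function(x, ...) {
  cat(sprintf("I/Q record: %d samples x %d segment(s) at %.3g MS/s\n",
              nrow(x$i), ncol(x$i), x$fs / 1e6))
  invisible(x)
}

#' Reference vibration record for ellipse calibration
#'
#' Renders the I/Q response to a sinusoidal surface vibration whose
#' amplitude exceeds the probe wavelength, so the interferometric phase
#' sweeps more than 4 pi and the I/Q locus closes into the full
#' calibration ellipse. Recorded before each measurement in practice; here
#' the generator plays that role.
#'
#' @param model An [iq_model()].
#' @param amplitude Vibration amplitude, m; must exceed `model$lambda` for
#'   a closed locus (warning otherwise).
#' @param freq Vibration frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param n_cycles Number of vibration cycles to record.
#' @param seed Optional noise seed.
#' @return An `iq_record` of one segment.
#' @export
make_reference_vibration <- function(model = iq_model(), amplitude = 5e-6,
                                     freq = 10e3, fs = 65e6, n_cycles = 2,
                                     seed = NULL) {
  stopifnot(inherits(model, "iq_model"), amplitude > 0)
  if (amplitude <= model$lambda)
    warning("reference amplitude below the probe wavelength: I/Q locus will not close")
  n <- max(64L, as.integer(round(n_cycles * fs / freq)))
  t <- (seq_len(n) - 1) / fs
  d <- amplitude * sin(2 * pi * freq * t)
  synthesize_iq(d, model, fs = fs, n_segments = 1, seed = seed,
                trigger_artifact = FALSE)
}

#' Line-scan acquisition settings
#'
#' @param pitch Scan pitch, m (125 um default, below the 204 um cutoff
#'   acoustic wavelength at 5 MHz).
#' @param n_positions Number of scan positions; computed from `length` if
#'   omitted.
#' @param length Scan length, m (used when `n_positions` is missing;
#'   1 cm at 125 um pitch gives 80 positions).
#' @param avg_duration Per-position averaging duration, s (1 s default).
#' @param rep_rate Excitation repetition rate, Hz; segments per position =
#'   `avg_duration * rep_rate`.
#' @param window Recorded window after each trigger, s.
#' @param seed Acquisition seed.
#' @return A `scan_config` list with derived `n_segments` and `positions`
#'   (centred on 0).
#' @export
scan_config <- function(pitch = 125e-6, n_positions = NULL, length = 1e-2,
                        avg_duration = 1, rep_rate = 1e3,
                        window = 20e-6, seed = NULL) {
  stopifnot(pitch > 0, avg_duration > 0)
  if (is.null(n_positions)) n_positions <- as.integer(round(length / pitch))
  n_positions <- as.integer(n_positions)
  stopifnot(n_positions >= 1)
  pos <- (seq_len(n_positions) - 1) * pitch
  pos <- pos - mean(pos)
  structure(list(pitch = pitch, n_positions = n_positions,
                 avg_duration = avg_duration, rep_rate = rep_rate,
                 n_segments = as.integer(round(avg_duration * rep_rate)),
                 window = window, positions = pos, seed = seed),
            class = "scan_config")
}

#' Generate a full synthetic line-scan dataset
#'
#' Runs the forward wave simulation once for the phantom, then renders a
#' distorted, noisy triggered I/Q record at every scan position from the
#' simulated surface displacement. Optionally applies a log-normal
#' position-dependent collection efficiency to the measurement amplitude,
#' mimicking variations in collected optical power across the surface.
#' Deterministic under a fixed seed.
#'
#' @param phantom A [phantom_spec()].
#' @param scan A [scan_config()].
#' @param model An [iq_model()].
#' @param seed Integer seed (overrides `scan$seed`).
#' @param dx Solver grid spacing, m.
#' @param f_max Grid resolution criterion frequency passed to
#'   [build_medium()].
#' @param fluence_scale See [initial_pressure_from_absorption()].
#' @param collection_spread Log-normal sigma of the per-position
#'   measurement amplitude multiplier (0 disables).
#' @param trigger_artifact Passed to [synthesize_iq()].
#' @param homogeneous Propagate in a uniform 1020 m/s slab (channel discs
#'   keep their initial pressure but not their 1500 m/s interior); used for
#'   reconstruction oracles consistent with the homogeneous reversal medium.
#' @return List with `records` (per-position `iq_record`s), the
#'   ground-truth `truth` ([simulate_forward()] record), `positions`,
#'   `medium`, `p0`, `scan`, `model` and `seed`.
#' @export
generate_scan_dataset <- function(phantom, scan = scan_config(),
                                  model = iq_model(), seed = NULL,
                                  dx = 20e-6, f_max = 5e6,
                                  fluence_scale = 1e3,
                                  collection_spread = 0,
                                  trigger_artifact = TRUE,
                                  homogeneous = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(scan, "scan_config"))
  if (is.null(seed)) seed <- scan$seed
  if (!is.null(seed)) set.seed(seed)
  width <- max(14e-3, diff(range(scan$positions)) + 4e-3)
  medium <- build_medium(phantom, dx = dx, width = width, f_max = f_max,
                         homogeneous = homogeneous)
  p0 <- initial_pressure_from_absorption(phantom, medium, fluence_scale)
  truth <- simulate_forward(medium, p0, duration = scan$window,
                            sensor_x = scan$positions)
  eff <- if (collection_spread > 0)
    rlnorm(scan$n_positions, sdlog = collection_spread) else
      rep(1, scan$n_positions)
  seeds <- if (!is.null(seed))
    sample.int(2^31 - 1, scan$n_positions) else rep(list(NULL), scan$n_positions)
  records <- vector("list", scan$n_positions)
  for (k in seq_len(scan$n_positions)) {
    mk <- model
    mk$m <- model$m * eff[k]
    mk$radius <- 2 * mk$mu * abs(mk$r * mk$m)
    records[[k]] <- synthesize_iq(truth$d[, k], mk, fs = truth$fs,
                                  n_segments = scan$n_segments,
                                  seed = if (is.null(seed)) NULL else seeds[[k]],
                                  rep_rate = scan$rep_rate,
                                  trigger_artifact = trigger_artifact)
  }
  list(records = records, truth = truth, positions = scan$positions,
       medium = medium, p0 = p0, scan = scan, model = model, seed = seed)
}
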