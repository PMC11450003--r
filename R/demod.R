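# I/Q ellipse correction, arctan phase demodulation, and the calibrated
# chain phase -> displacement -> velocity -> pressure

#' Demodulation configuration
#'
#' @param lambda Probe wavelength in m (1550 nm).
#' @param fs Sampling rate of the I/Q record in Hz.
#' @param cutoff Low-pass cutoff applied to the velocity estimate, Hz.
#' @param order Butterworth order of that filter (applied forward-backward,
#'   zero phase).
#' @param impedance Acoustic impedance of the sample surface, Rayl
#'   (1.02 MRayl for PDMS); converts surface velocity to incident pressure
#'   as p = Z u / 2.
#' @param dropout Radius threshold below which corrected I/Q samples are
#'   treated as signal dropouts and interpolated.
#' @return A `demod_config` list.
#' @export
demod_config <- function(lambda = 1550e-9, fs = 65e6, cutoff = 5e6,
                         order = 4, impedance = 1.02e6, dropout = 0.05) {
  stopifnot(lambda > 0, fs > 0, cutoff > 0, order >= 1)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  structure(list(lambda = lambda, fs = fs, cutoff = cutoff, order = order,
                 impedance = impedance, dropout = dropout),
            class = "demod_config")
}

#' Direct least-squares ellipse fit to I/Q samples
#'
#' Fits the conic a x^2 + b xy + c y^2 + d x + e y + f = 0 under the
#' ellipse constraint 4ac - b^2 = 1 (direct least-squares / generalized
#' eigenvalue formulation), then converts to geometric parameters. Used on
#' a reference record of a large (> wavelength) vibration whose I/Q locus
#' closes into the full calibration ellipse.
#'
#' @param i,q In-phase and quadrature samples (equal-length vectors). `i`
#'   may also be a two-column matrix/list holding both.
#' @return An `ellipse_params` object: `center` (I, Q), semi-axes `a >= b`,
#'   tilt `phi` (rad, angle of the major axis), and `residual` (RMS
#'   algebraic distance of the samples to the fitted conic, normalized).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 400)
#' fit_ellipse(1.2 * cos(th) + 0.1, 0.8 * sin(th) - 0.05)
#' @export
fit_ellipse <- function(i, q = NULL) {
  if (is.null(q)) { q <- i[[2]]; i <- i[[1]] }
  stopifnot(length(i) == length(q))
  if (length(i) < 6) stop("ellipse fit needs at least 6 points")
  mx <- mean(i); my <- mean(q)
  sc <- mean(sqrt((i - mx)^2 + (q - my)^2))
  if (sc < .Machine$double.eps)
    stop("degenerate I/Q input: zero spread")
  x <- (i - mx) / sc; y <- (q - my) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate I/Q input: collinear or tiny-arc samples"))
  M <- S1 + S2 %*% T3
  # constraint matrix inverse action: C = [[0,0,2],[0,-1,0],[2,0,0]]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0)
    stop("no ellipse solution: input arc too small or collinear")
  a1 <- evec[, ok[1]]
  coef <- c(a1, T3 %*% a1)        # (A, B, C, D, E, F) in scaled frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; FF <- coef[6]

  den <- B^2 - 4 * A * C                 # < 0 for an ellipse
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * FF)
  s <- sqrt((A - C)^2 + B^2)
  aa <- -sqrt(abs(num * ((A + C) + s))) / den
  bb <- -sqrt(abs(num * ((A + C) - s))) / den
  semi <- sort(c(aa, bb), decreasing = TRUE)
  phi <- 0.5 * atan2(-B, C - A)          # major-axis angle in (-pi/2, pi/2]
  if (aa < bb) phi <- phi + pi / 2
  if (phi > pi / 2) phi <- phi - pi
  if (phi <= -pi / 2) phi <- phi + pi

  resid <- sqrt(mean((D1 %*% coef[1:3] + D2 %*% coef[4:6])^2)) /
    sqrt(sum(coef[1:3]^2))
  structure(list(center = c(mx + sc * cx, my + sc * cy),
                 a = sc * semi[1], b = sc * semi[2],
                 phi = phi, residual = resid),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "ellipse: center (%.4g, %.4g), semi-axes %.4g / %.4g, tilt %.2f deg, residual %.2g\n",
    x$center[1], x$center[2], x$a, x$b, 180 / pi * x$phi, x$residual))
  invisible(x)
}

#' Project distorted I/Q samples onto the unit circle
#'
#' Heydemann-style quadrature correction: translate by minus the fitted
#' ellipse centre, rotate by minus the tilt, rescale the semi-axes to 1,
#' rotate back. Noiseless on-ellipse points land exactly on the unit
#' circle; the demodulated phase is preserved up to the calibrated
#' distortion.
#'
#' @param i,q Distorted samples (vectors or samples x segments matrices).
#' @param ellipse An [fit_ellipse()] result.
#' @return List with corrected `i` and `q`.
#' @export
correct_iq <- function(i, q, ellipse) {
  stopifnot(inherits(ellipse, "ellipse_params"))
  cp <- cos(ellipse$phi); sp <- sin(ellipse$phi)
  x <- i - ellipse$center[1]; y <- q - ellipse$center[2]
  u <- ( cp * x + sp * y) / ellipse$a
  v <- (-sp * x + cp * y) / ellipse$b
  list(i = cp * u - sp * v, q = sp * u + cp * v)
}

#' Four-quadrant phase demodulation with unwrapping
#'
#' Computes atan2(Q, I) per sample and unwraps 2 pi jumps along time.
#' Samples whose I/Q radius falls below the dropout threshold (loss of
#' optical signal) are linearly interpolated and counted.
#'
#' @param i,q Corrected I/Q samples (vectors or samples x segments
#'   matrices; columns are processed independently).
#' @param dropout Radius threshold for dropout flagging.
#' @return Unwrapped phase (same shape), with attribute `dropouts` giving
#'   the number of interpolated samples.
#' @export
demodulate_phase <- function(i, q, dropout = 0.05) {
  vec <- !is.matrix(i)
  i <- as.matrix(i); q <- as.matrix(q)
  r <- sqrt(i^2 + q^2)
  theta <- atan2(q, i)
  theta <- .unwrap_cols(theta)
  bad <- r < dropout
  ndrop <- sum(bad)
  if (ndrop > 0) {
    for (k in which(colSums(bad) > 0)) {
      idx <- which(!bad[, k])
      if (length(idx) < 2) stop("all samples in a segment are dropouts")
      theta[, k] <- approx(idx, theta[idx, k], xout = seq_len(nrow(theta)),
                           rule = 2)$y
    }
  }
  if (vec) theta <- drop(theta)
  attr(theta, "dropouts") <- ndrop
  theta
}

#' Displacement from interferometric phase
#'
#' d(t) = lambda * (theta(t) - theta(1)) / (4 pi): each 2 pi of
#' double-pass optical phase corresponds to half a wavelength of surface
#' motion. The first sample defines zero displacement (only relative
#' motion is meaningful in homodyne detection).
#'
#' @param theta Unwrapped phase (vector or samples x segments matrix).
#' @param lambda Probe wavelength in m.
#' @return Displacement in m, same shape.
#' @export
phase_to_displacement <- function(theta, lambda = 1550e-9) {
  theta <- as.matrix(theta)
  ref <- theta[1, ]
  d <- lambda * sweep(theta, 2, ref) / (4 * pi)
  if (ncol(d) == 1) drop(d) else d
}

#' Surface velocity from displacement
#'
#' Central-difference time derivative followed by a zero-phase Butterworth
#' low pass at the configured cutoff (5 MHz default) to limit the
#' differentiation noise.
#'
#' @param d Displacement (vector or samples x traces matrix), m.
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz.
#' @param order Butterworth order.
#' @return Velocity in m/s, same shape.
#' @export
displacement_to_velocity <- function(d, fs, cutoff = 5e6, order = 4) {
  vec <- !is.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3 * (order + 1))
    stop("trace too short for derivative + filter warm-up")
  dt <- 1 / fs
  u <- apply(d, 2, function(col) {
    du <- numeric(n)
    du[2:(n - 1)] <- (col[3:n] - col[1:(n - 2)]) / (2 * dt)
    du[1] <- (col[2] - col[1]) / dt
    du[n] <- (col[n] - col[n - 1]) / dt
    du
  })
  u <- lowpass_zero_phase(u, fs, cutoff, order)
  if (vec) drop(u) else u
}

#' Zero-phase Butterworth low pass
#'
#' @param x Vector or samples x traces matrix.
#' @param fs Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order (applied forward and backward).
#' @return Filtered data, same shape.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.matrix(x)) apply(x, 2, function(col) signal::filtfilt(bf, col))
  else signal::filtfilt(bf, x)
}

#' Incident pressure from surface velocity
#'
#' For a wave arriving at a free (pressure-release) surface of a medium
#' with impedance Z much larger than air, the surface moves at twice the
#' incident particle velocity, so p = (Z / 2) u.
#'
#' @param u Surface velocity (any numeric shape), m/s.
#' @param impedance Acoustic impedance Z of the sample, Rayl.
#' @return Pressure, Pa, same shape as `u`.
#' @export
velocity_to_pressure <- function(u, impedance = 1.02e6) {
  impedance / 2 * u
}

#' Trigger-aligned segment averaging
#'
#' Averages equal-length, trigger-aligned segments (columns). Averaging N
#' segments of identical signal plus independent noise improves the noise
#' RMS by sqrt(N).
#'
#' @param x Samples x segments matrix (a vector is returned unchanged).
#' @return Averaged trace (vector).
#' @export
average_segments <- function(x) {
  if (!is.matrix(x)) return(x)
  if (ncol(x) == 0) stop("no segments to average")
  rowMeans(x)
}

#' Full demodulation of an I/Q record
#'
#' Runs the complete processing chain on a triggered I/Q record:
#' per-segment ellipse correction, arctan demodulation, unwrapping and
#' conversion to displacement; trigger-aligned averaging of the
#' displacement traces; then differentiation with zero-phase low-pass to
#' velocity, scaling to pressure, and Hilbert envelopes. Segments are
#' demodulated before averaging because averaging raw I/Q would bias the
#' result through the arctan nonlinearity.
#'
#' @param record An [synthesize_iq()] record (or any list with `i`, `q`
#'   samples x segments matrices and `fs`).
#' @param config A [demod_config()].
#' @param ellipse Calibration ellipse from a reference vibration
#'   ([fit_ellipse()] on [make_reference_vibration()]); if `NULL`, fitted
#'   from the record itself (adequate only when the record's own locus
#'   closes).
#' @return A `demod_result`: `time`, unwrapped mean phase `theta`,
#'   displacement `d` (m), velocity `u` (m/s), pressure `p` (Pa), envelopes
#'   `env_u`, `env_p`, number of interpolated `dropouts` and `n_segments`.
#' @export
demodulate_record <- function(record, config = demod_config(),
                              ellipse = NULL) {
  stopifnot(inherits(config, "demod_config"))
  i <- as.matrix(record$i); q <- as.matrix(record$q)
  fs <- if (!is.null(record$fs)) record$fs else config$fs
  if (is.null(ellipse)) ellipse <- fit_ellipse(as.vector(i), as.vector(q))
  corr <- correct_iq(i, q, ellipse)
  theta <- demodulate_phase(corr$i, corr$q, dropout = config$dropout)
  ndrop <- attr(theta, "dropouts")
  d_seg <- phase_to_displacement(theta, lambda = config$lambda)
  d <- average_segments(as.matrix(d_seg))
  u <- displacement_to_velocity(d, fs, cutoff = config$cutoff,
                                order = config$order)
  p <- velocity_to_pressure(u, impedance = config$impedance)
  structure(list(time = (seq_along(d) - 1) / fs,
                 theta = rowMeans(as.matrix(theta)),
                 d = d, u = u, p = p,
                 env_u = envelope(u), env_p = envelope(p),
                 dropouts = ndrop, n_segments = ncol(i), fs = fs,
                 config = config, ellipse = ellipse),
            class = "demod_result")
}

#' @export
print.demod_result <- function(x, ...) {
  cat(sprintf(
    "demodulated trace: %d samples at %.3g MS/s, %d segment(s) averaged, %d dropout sample(s)\n",
    length(x$d), x$fs / 1e6, x$n_segments, x$dropouts))
  cat(sprintf("  peak |u| = %.3g mm/s, peak |p| = %.3g kPa\n",
              1e3 * max(abs(x$u)), 1e-3 * max(abs(x$p))))
  invisible(x)
}

#' @export
plot.demod_result <- function(x, ...) {
  graphics::plot(1e6 * x$time, 1e3 * x$u, type = "l",
                 xlab = "time (us)", ylab = "surface velocity (mm/s)", ...)
  lines(1e6 * x$time, 1e3 * x$env_u, col = 2)
  legend("topright", c("velocity", "envelope"), col = 1:2, lty = 1, bty = "n")
  invisible(x)
}
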