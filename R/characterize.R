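# detector performance metrics: noise spectra, NEV/NEP, sensitivity,
# bandwidth, SNR

#' Noise-equivalent-velocity spectrum of a still-sample recording
#'
#' Welch PSD of a demodulated velocity trace recorded on a still sample;
#' the square root of the one-sided velocity PSD is the NEV spectral
#' density in (m/s)/sqrt(Hz).
#'
#' @param u Velocity trace, m/s.
#' @param fs Sampling rate, Hz.
#' @param nperseg,overlap,window Welch settings (Hann, 50 % overlap,
#'   2^14-sample segments by default).
#' @return A `noise_spectrum`: `freq`, `psd` ((m/s)^2/Hz), `nev_density`
#'   (its square root) and the settings used.
#' @export
nev_spectrum <- function(u, fs, nperseg = 2^14, overlap = 0.5,
                         window = "hann") {
  w <- welch_psd(u, fs, nperseg = nperseg, overlap = overlap, window = window)
  structure(list(freq = w$freq, psd = w$psd, nev_density = sqrt(w$psd),
                 fs = fs, settings = w$settings),
            class = "noise_spectrum")
}

#' @export
print.noise_spectrum <- function(x, ...) {
  cat(sprintf("velocity noise spectrum: %d bins to %.3g MHz (%d Welch segments)\n",
              length(x$freq), max(x$freq) / 1e6, x$settings$nseg))
  invisible(x)
}

#' Band-integrated NEV and NEP
#'
#' Total noise-equivalent velocity over a band, NEV =
#' sqrt(integral of the velocity PSD), and the corresponding
#' noise-equivalent pressure NEP = (Z/2) NEV via the free-surface
#' pressure-velocity relation.
#'
#' @param spec A [nev_spectrum()] result.
#' @param band Two-element band limits in Hz (default 0 to 5 MHz, the
#'   digital low-pass band of the processing chain).
#' @param impedance Sample impedance, Rayl.
#' @return List with `nev` (m/s) and `nep` (Pa).
#' @examples
#' # a detector with NEV 4 mm/s on a 1.02 MRayl sample has NEP ~ 2 kPa:
#' 1.02e6 / 2 * 4e-3
#' @export
integrate_nev <- function(spec, band = c(0, 5e6), impedance = 1.02e6) {
  stopifnot(inherits(spec, "noise_spectrum"), length(band) == 2)
  if (band[2] > max(spec$freq) + diff(spec$freq[1:2]) / 2)
    stop("band extends beyond the spectrum")
  df <- diff(spec$freq[1:2])
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  nev <- sqrt(sum(spec$psd[sel]) * df)
  list(nev = nev, nep = impedance / 2 * nev)
}

#' Sensitivity spectrum of a candidate detector against a reference
#'
#' S(f) = |C(f)| / |P(f)| where C and P are the FFT magnitude spectra of
#' the same acoustic event recorded by the candidate and the reference
#' detector. Bins where the reference magnitude does not exceed
#' `floor_factor` times the local noise-floor estimate (running median of
#' |P|) are masked as invalid.
#'
#' @param candidate,reference Time traces on a common time base.
#' @param fs Sampling rate, Hz.
#' @param floor_factor Validity threshold over the local noise floor.
#' @param floor_window Running-median window (bins) for the floor estimate.
#' @return A `sens_spectrum`: `freq`, `S`, `C`, `P`, logical `valid` mask.
#' @export
sensitivity_spectrum <- function(candidate, reference, fs,
                                 floor_factor = 5, floor_window = NULL) {
  stopifnot(length(candidate) == length(reference))
  if (all(reference == 0)) stop("reference trace is identically zero")
  n <- length(reference)
  nf <- n %/% 2 + 1
  Cm <- Mod(fft(candidate)[1:nf])
  Pm <- Mod(fft(reference)[1:nf])
  if (is.null(floor_window)) floor_window <- max(9L, as.integer(nf / 16))
  if (floor_window %% 2 == 0) floor_window <- floor_window + 1L
  floor_est <- stats::runmed(Pm, floor_window, endrule = "median")
  # a bin is valid where the reference stands above floor_factor x the
  # local floor estimate; for smooth noiseless spectra the running median
  # tracks the signal itself, so cap the threshold relative to the peak
  valid <- Pm >= pmin(floor_factor * floor_est, max(Pm) * 1e-3) &
    Pm > max(Pm) * 1e-6
  S <- ifelse(valid, Cm / Pm, NA_real_)
  structure(list(freq = (seq_len(nf) - 1) * fs / n, S = S,
                 C = Cm, P = Pm, valid = valid),
            class = "sens_spectrum")
}

#' 3 dB bandwidth of a sensitivity spectrum
#'
#' Finds the lowest frequency at which S(f) falls 3 dB (a factor 1/sqrt(2)
#' in amplitude) below its low-frequency plateau, taken as the median of
#' the valid S below 1 MHz.
#'
#' @param spec A [sensitivity_spectrum()] result.
#' @param plateau_below Upper frequency (Hz) of the plateau estimate.
#' @return The 3 dB frequency in Hz. If S never crosses -3 dB inside the
#'   valid band, the highest valid frequency is returned with attribute
#'   `flag = "no-crossing"`.
#' @export
bandwidth_3db <- function(spec, plateau_below = 1e6) {
  stopifnot(inherits(spec, "sens_spectrum"))
  low <- spec$valid & spec$freq <= plateau_below
  if (!any(low)) stop("no valid bins below the plateau frequency")
  plateau <- median(spec$S[low])
  thr <- plateau / sqrt(2)
  idx <- which(spec$valid & spec$S < thr & spec$freq > 0)
  if (length(idx) == 0) {
    f <- max(spec$freq[spec$valid])
    attr(f, "flag") <- "no-crossing"
    return(f)
  }
  k <- idx[1]
  # linear interpolation to the crossing within the previous valid bin
  prev <- max(which(spec$valid[seq_len(k - 1)]))
  f1 <- spec$freq[prev]; f2 <- spec$freq[k]
  s1 <- spec$S[prev]; s2 <- spec$S[k]
  if (is.finite(s1) && s1 > thr && s2 < s1)
    f1 + (s1 - thr) / (s1 - s2) * (f2 - f1)
  else f2
}

#' Signal-to-noise ratio of a photoacoustic pulse trace
#'
#' Maximum of the Hilbert envelope of the trace divided by the RMS of the
#' samples inside a signal-free noise window (an interval before the
#' acoustic arrival, excluding the trigger interference transient).
#'
#' @param trace Velocity (or pressure) time trace.
#' @param fs Sampling rate, Hz.
#' @param noise_window Two-element time interval in s containing noise
#'   only.
#' @param signal_window Optional two-element interval in s within which
#'   the pulse envelope maximum is taken (defaults to the whole trace);
#'   used to keep the t = 0 trigger interference out of the pulse search.
#' @return The SNR (dimensionless amplitude ratio).
#' @export
snr <- function(trace, fs, noise_window, signal_window = NULL) {
  stopifnot(length(noise_window) == 2, noise_window[2] > noise_window[1])
  t <- (seq_along(trace) - 1) / fs
  sel <- t >= noise_window[1] & t <= noise_window[2]
  if (!any(sel)) stop("noise window contains no samples")
  nrms <- sqrt(mean(trace[sel]^2))
  if (nrms == 0) stop("noise window has zero RMS: cannot form an SNR")
  env <- envelope(trace)
  if (!is.null(signal_window)) {
    keep <- t >= signal_window[1] & t <= signal_window[2]
    if (!any(keep)) stop("signal window contains no samples")
    env <- env[keep]
  }
  max(env) / nrms
}

#' Excitation pulse energy and average power
#'
#' @param peak_power Peak optical power, W.
#' @param width Pulse width, s.
#' @param rep_rate Repetition rate, Hz.
#' @return List with `energy` (J) and `avg_power` (W).
#' @examples
#' excitation_summary(500, 400e-9, 1e3)  # 200 uJ, 0.2 W
#' @export
excitation_summary <- function(peak_power = 500, width = 400e-9,
                               rep_rate = 1e3) {
  stopifnot(peak_power > 0, width > 0, rep_rate > 0)
  e <- peak_power * width
  list(energy = e, avg_power = e * rep_rate)
}
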