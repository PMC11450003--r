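# small FFT-based signal primitives shared across modules

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal x + i H\{x\} (negative frequencies
#' zeroed, positive doubled).
#'
#' @param x Real vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty trace")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform envelope of a trace
#'
#' Magnitude of the analytic signal; the nonnegative amplitude envelope of
#' a band-limited pulse.
#'
#' @param x Real vector (or samples x traces matrix; applied per column).
#' @return Nonnegative envelope, same shape as `x`.
#' @export
envelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, envelope))
  Mod(analytic_signal(x))
}

# vectorized 2*pi phase unwrap along columns
.unwrap_cols <- function(theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) < 2) return(theta)
  dp <- diff(theta)
  corr <- -2 * pi * round(dp / (2 * pi))
  corr[abs(dp) <= pi] <- 0
  theta + rbind(0, apply(corr, 2, cumsum))
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram over overlapping Hann-windowed segments, one-sided
#' density scaling (integral of the PSD over frequency equals the signal
#' variance for zero-mean input).
#'
#' @param x Real vector.
#' @param fs Sampling rate in Hz.
#' @param nperseg Segment length in samples.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @param window Window type, `"hann"` or `"rect"`.
#' @param demean Subtract the mean before estimating.
#' @return List with `freq` (Hz) and `psd` (x^2/Hz), one-sided.
#' @export
welch_psd <- function(x, fs, nperseg = 2^14, overlap = 0.5,
                      window = c("hann", "rect"), demean = TRUE) {
  window <- match.arg(window)
  n <- length(x)
  if (n < nperseg)
    stop(sprintf("trace (%d samples) shorter than one Welch segment (%d)", n, nperseg))
  if (demean) x <- x - mean(x)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1))) else rep(1, nperseg)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  nf <- nperseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    P <- Mod(fft(seg)[1:nf])^2
    acc <- acc + P
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  psd <- acc * scale
  # one-sided: double all bins except DC (and Nyquist when present)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd,
       settings = list(nperseg = nperseg, overlap = overlap,
                       window = window, nseg = length(starts)))
}
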