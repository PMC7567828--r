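# Shared DSP kernels: zero-phase FIR band-pass, Hilbert envelope, Welch PSD,
# band power and normalized cross-correlation.

next_fast_len <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# Apply a linear-phase FIR filter b forward and reverse (zero net phase) via
# FFT multiplication by |B(w)|^2, with mirror padding so edge transients fall
# in the padding. Exactly equivalent to convolving with conv(b, rev(b)).
zerophase_fir_apply <- function(x, b) {
  n <- length(x)
  L <- length(b)
  pad <- min(n - 1L, L)
  xm <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  N <- next_fast_len(length(xm) + 2L * L)
  B <- stats::fft(c(b, rep(0, N - L)))
  X <- stats::fft(c(xm, rep(0, N - length(xm))))
  y <- Re(stats::fft(X * (Mod(B)^2), inverse = TRUE)) / N
  y[(pad + 1L):(pad + n)]
}

# Scale a filter order defined at 1000 Hz to another sampling rate.
scale_fir_order <- function(order_at_1k, rate) {
  ord <- as.integer(round(order_at_1k * rate / 1000))
  max(2L, ord)
}

#' Zero-phase FIR band-pass filter
#'
#' Window-based (Hamming) FIR design applied in both the forward and reverse
#' directions, so the net phase is zero: a passband tone is not shifted in
#' time. The reference orders (333 for the 9-16 Hz spindle band, 6000 for the
#' 0.5-4 Hz slow-wave band) are defined at 1000 Hz and scaled proportionally
#' for other rates when \code{order} is given as \code{order_at_1k}.
#'
#' @param signal An \code{eeg_signal}.
#' @param band Numeric length-2 vector \code{c(lo, hi)} in Hz.
#' @param order FIR order (taps - 1). Must be below a third of the signal
#'   length.
#' @param order_at_1k Alternative to \code{order}: an order defined at
#'   1000 Hz, scaled by \code{rate/1000}.
#' @return Filtered \code{eeg_signal}, same length.
#' @examples
#' t <- seq(0, 4, by = 1e-3)
#' s <- eeg_signal(sin(2 * pi * 12 * t), 1000)
#' f <- fir_bandpass(s, c(9, 16), order = 333)
#' @export
fir_bandpass <- function(signal, band, order = NULL, order_at_1k = NULL) {
  stopifnot(inherits(signal, "eeg_signal"))
  band <- check_band(band, signal$rate)
  if (is.null(order)) {
    if (is.null(order_at_1k)) stop("give order or order_at_1k")
    order <- scale_fir_order(order_at_1k, signal$rate)
  }
  if (order >= length(signal$samples) / 3)
    stop("filter order too large for signal length")
  b <- signal::fir1(order, band / (signal$rate / 2), "pass")
  y <- zerophase_fir_apply(signal$samples, as.numeric(b))
  eeg_signal(y, rate = signal$rate, label = signal$label, t0 = signal$t0)
}

check_band <- function(band, rate) {
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= rate / 2)
    stop("band must satisfy 0 < lo < hi < rate/2")
  band
}

#' Instantaneous amplitude via the Hilbert transform
#'
#' Returns the magnitude of the analytic signal (FFT construction), i.e. the
#' instantaneous amplitude envelope; used to extract the spindle envelope from
#' the 9-16 Hz filtered trace.
#'
#' @param signal An \code{eeg_signal}.
#' @return \code{eeg_signal} holding the nonnegative envelope, same length.
#' @export
hilbert_envelope <- function(signal) {
  stopifnot(inherits(signal, "eeg_signal"))
  x <- signal$samples
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  eeg_signal(env, rate = signal$rate, label = signal$label, t0 = signal$t0)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density
#'
#' One-sided PSD from Hann-windowed overlapping segments (default 8-s
#' segments, 75\% overlap).
#'
#' @param signal An \code{eeg_signal} of at least one window length.
#' @param window_s Segment length in seconds (default 8).
#' @param overlap Fractional overlap between segments (default 0.75).
#' @return List with \code{freq} (Hz) and \code{psd} (uV^2/Hz).
#' @export
welch_psd <- function(signal, window_s = 8, overlap = 0.75) {
  stopifnot(inherits(signal, "eeg_signal"))
  x <- signal$samples
  fs <- signal$rate
  nw <- as.integer(round(window_s * fs))
  if (length(x) < nw) stop("signal shorter than one Welch window")
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  w <- hann_window(nw)
  U <- sum(w^2)
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  acc <- numeric(nw)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  P <- acc / (length(starts) * fs * U)
  half <- seq_len(nw %/% 2 + 1L)
  psd <- P[half]
  # double all bins except DC (and Nyquist for even nw)
  dbl <- 2:(if (nw %% 2L == 0L) nw %/% 2 else nw %/% 2 + 1L)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (half - 1) * fs / nw, psd = psd)
}

#' Band power of a segment (modified periodogram)
#'
#' Integral of the Hann-windowed periodogram over a frequency band; for a pure
#' sine of amplitude A inside the band this is approximately A^2/2.
#'
#' @param x Numeric segment (uV) or \code{eeg_signal}.
#' @param rate Sampling rate (Hz); ignored when \code{x} is an
#'   \code{eeg_signal}.
#' @param band \code{c(lo, hi)} in Hz, inside the Nyquist range.
#' @return Power in uV^2.
#' @export
bandpower <- function(x, band, rate = NULL) {
  if (inherits(x, "eeg_signal")) { rate <- x$rate; x <- x$samples }
  if (is.null(rate)) stop("rate required")
  band <- check_band(band, rate)
  n <- length(x)
  if (all(x == 0)) return(0)
  w <- hann_window(n)
  X <- Mod(stats::fft(x * w))^2
  U <- sum(w^2)
  P <- X / (rate * U)
  half <- seq_len(n %/% 2 + 1L)
  P <- P[half]
  dbl <- 2:(if (n %% 2L == 0L) n %/% 2 else n %/% 2 + 1L)
  P[dbl] <- 2 * P[dbl]
  freq <- (half - 1) * rate / n
  df <- rate / n
  sum(P[freq >= band[1] & freq <= band[2]]) * df
}

#' Normalized cross-correlation with lag search
#'
#' \code{r(lag) = sum (a - mean(a)) * (b_shifted - mean(b)) /
#' sqrt(sum (a - mean(a))^2 * sum (b - mean(b))^2)}, evaluated over integer
#' sample lags up to \code{max_lag}; positive lag means \code{b} trails
#' \code{a} (e.g. spikes following the LFP peak).
#'
#' @param a,b Numeric vectors on the same sampling grid.
#' @param max_lag Maximum lag in samples (< length/2).
#' @param rate Sampling rate in Hz used to report the peak lag in ms.
#' @return List with \code{lags} (samples), \code{r}, \code{peak}
#'   (maximum r), \code{peak_lag_ms}.
#' @export
normalized_xcorr <- function(a, b, max_lag, rate) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (max_lag >= n / 2) stop("max_lag must be below half the series length")
  ac <- a - mean(a); bc <- b - mean(b)
  den <- sqrt(sum(ac^2) * sum(bc^2))
  if (den == 0) stop("zero-variance input")
  lags <- (-max_lag):max_lag
  r <- vapply(lags, function(l) {
    if (l >= 0) sum(ac[seq_len(n - l)] * bc[seq_len(n - l) + l])
    else sum(ac[seq_len(n + l) - l] * bc[seq_len(n + l)])
  }, numeric(1)) / den
  i <- which.max(r)
  list(lags = lags, r = r, peak = r[i], peak_lag_ms = lags[i] / rate * 1000)
}
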