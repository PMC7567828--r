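# Continuous wavelet transform, implemented in the frequency domain per
# analysis frequency. Each mother wavelet is defined by the magnitude of its
# Fourier transform on the positive half-axis (analytic convention); rows are
# L2-normalized per scale so wavelet energy is comparable across scales and
# homogeneous of degree 2 in signal amplitude.
#
# The detection wavelet is the complex frequency B-spline
#   psi(t) = sqrt(fb) * sinc(fb*t/m)^m * exp(2*pi*i*fc*t),
# whose spectrum is a B-spline of order m: compactly supported on
# fc +/- fb/2. That compact frequency support (zero response to out-of-band
# 1/f energy) is what distinguishes it from the Gaussian-tailed complex
# Morlet in the spindle band.

# central B-spline of order m (m-fold convolution of the unit rect),
# support |x| <= m/2
bspline_central <- function(x, m) {
  if (m == 1L) return(as.numeric(abs(x) < 0.5) + 0.5 * (abs(x) == 0.5))
  k <- 0:m
  out <- numeric(length(x))
  for (kk in k) {
    u <- x + m / 2 - kk
    out <- out + (-1)^kk * choose(m, kk) * ifelse(u > 0, u^(m - 1), 0)
  }
  out <- out / factorial(m - 1)
  # the truncated-power sum cancels only to rounding error outside the
  # compact support [-m/2, m/2]; enforce exact zeros there
  out[abs(x) > m / 2] <- 0
  out
}

# Families: each entry is fhat(f, p) -> |psi_hat(f)| for f > 0 (natural
# frequency units), plus which free parameters apply.
wavelet_families <- function() {
  w <- 2 * pi
  list(
    fbsp = list(
      params = c("order_m", "bandwidth_fb", "center_fc"),
      fhat = function(f, p) bspline_central((f - p$center_fc) *
                                            p$order_m / p$bandwidth_fb,
                                            p$order_m)
    ),
    cmor = list(
      params = c("bandwidth_fb", "center_fc"),
      fhat = function(f, p) exp(-pi^2 * p$bandwidth_fb *
                                  (f - p$center_fc)^2)
    ),
    shan = list(
      params = c("bandwidth_fb", "center_fc"),
      fhat = function(f, p) as.numeric(abs(f - p$center_fc) <=
                                         p$bandwidth_fb / 2)
    ),
    morl = list(params = character(),
                fhat = function(f, p) exp(-(w * f - 5)^2 / 2)),
    mexh = list(params = character(),
                fhat = function(f, p) (w * f)^2 * exp(-(w * f)^2 / 2)),
    gaus1 = list(params = character(),
                 fhat = function(f, p) (w * f) * exp(-(w * f)^2 / 2)),
    gaus2 = list(params = character(),
                 fhat = function(f, p) (w * f)^2 * exp(-(w * f)^2 / 2)),
    gaus3 = list(params = character(),
                 fhat = function(f, p) (w * f)^3 * exp(-(w * f)^2 / 2)),
    gaus4 = list(params = character(),
                 fhat = function(f, p) (w * f)^4 * exp(-(w * f)^2 / 2)),
    cgau1 = list(params = character(),
                 fhat = function(f, p) (w * f) * exp(-(w * f - 1)^2 / 4)),
    cgau2 = list(params = character(),
                 fhat = function(f, p) (w * f)^2 * exp(-(w * f - 1)^2 / 4)),
    cgau4 = list(params = character(),
                 fhat = function(f, p) (w * f)^4 * exp(-(w * f - 1)^2 / 4)),
    paul2 = list(params = character(),
                 fhat = function(f, p) (w * f)^2 * exp(-w * f)),
    paul4 = list(params = character(),
                 fhat = function(f, p) (w * f)^4 * exp(-w * f)),
    haar = list(params = character(),
                fhat = function(f, p) {
                  q <- w * f / 4
                  ifelse(q == 0, 0, sin(q)^2 / q)
                })
  )
}

#' Names of the supported wavelet families
#' @return Character vector of family names usable in
#'   \code{\link{wavelet_spec}} (15 families; \code{"fbsp"} is the complex
#'   frequency B-spline, \code{"cmor"} the complex Morlet).
#' @export
wavelet_family_names <- function() names(wavelet_families())

#' Specify a mother wavelet
#'
#' @param family Family name (see \code{\link{wavelet_family_names}}).
#' @param order_m B-spline order (fbsp only), >= 1.
#' @param bandwidth_fb Bandwidth shape parameter, > 0 (fbsp/cmor/shan).
#' @param center_fc Center frequency in natural units, > 0 (fbsp/cmor/shan);
#'   for the fixed families the center frequency is located numerically from
#'   the spectrum peak.
#' @return Object of class \code{wavelet_spec}.
#' @examples
#' wavelet_spec("fbsp", order_m = 2, bandwidth_fb = 1, center_fc = 1)
#' @export
wavelet_spec <- function(family = "fbsp", order_m = 2, bandwidth_fb = 1.0,
                         center_fc = 1.0) {
  fams <- wavelet_families()
  if (!family %in% names(fams))
    stop("unsupported wavelet family: ", family)
  if (order_m < 1 || order_m != round(order_m)) stop("order_m must be a positive integer")
  if (bandwidth_fb <= 0) stop("bandwidth_fb must be > 0")
  if (center_fc <= 0) stop("center_fc must be > 0")
  p <- list(order_m = as.integer(order_m), bandwidth_fb = bandwidth_fb,
            center_fc = center_fc)
  fdef <- fams[[family]]
  fc <- if ("center_fc" %in% fdef$params) {
    center_fc
  } else {
    grid <- seq(1e-3, 4, length.out = 8000)
    grid[which.max(fdef$fhat(grid, p))]
  }
  structure(list(family = family, order_m = p$order_m,
                 bandwidth_fb = bandwidth_fb, center_fc = center_fc,
                 fc_effective = fc, fhat = fdef$fhat, p = p),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s (m=%d, fb=%g, fc=%g; effective fc=%.3f)\n",
              x$family, x$order_m, x$bandwidth_fb, x$center_fc,
              x$fc_effective))
  invisible(x)
}

# Evaluate the L2-normalized scaled wavelet filter on an FFT frequency grid
# for analysis frequency f0 (Hz). Scale a = fc_eff / f0; filter is
# sqrt(a) * psi_hat(a*f), then normalized to unit discrete L2 energy.
wavelet_row_filter <- function(wavelet, f0, fgrid, df) {
  a <- wavelet$fc_effective / f0
  H <- numeric(length(fgrid))
  pos <- fgrid > 0
  H[pos] <- sqrt(a) * wavelet$fhat(a * fgrid[pos], wavelet$p)
  nrm <- sqrt(sum(H^2) * df)
  if (nrm == 0) stop("degenerate wavelet filter at ", f0, " Hz")
  H / nrm
}

# Shared frequency-domain CWT engine. reduce = "none" returns the complex
# coefficient matrix (freq x time); "mean_energy" accumulates the mean of
# |coef|^2 across rows without storing them.
cwt_engine <- function(x, rate, wavelet, frequencies, reduce = "none") {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(4 * rate / min(frequencies))))
  xm <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  N <- next_fast_len(length(xm))
  xm <- c(xm, rep(0, N - length(xm)))
  X <- stats::fft(xm)
  k <- 0:(N - 1)
  fgrid <- ifelse(k <= N / 2, k, k - N) * rate / N
  df <- rate / N
  sel <- (pad + 1L):(pad + n)
  if (reduce %in% c("mean_energy", "max_energy")) {
    acc <- numeric(n)
    for (f0 in frequencies) {
      H <- wavelet_row_filter(wavelet, f0, fgrid, df)
      row <- stats::fft(X * H, inverse = TRUE) / N
      e <- Mod(row[sel])^2
      acc <- if (reduce == "mean_energy") acc + e else pmax(acc, e)
    }
    return(if (reduce == "mean_energy") acc / length(frequencies) else acc)
  }
  out <- matrix(0i, nrow = length(frequencies), ncol = n)
  for (i in seq_along(frequencies)) {
    H <- wavelet_row_filter(wavelet, frequencies[i], fgrid, df)
    row <- stats::fft(X * H, inverse = TRUE) / N
    out[i, ] <- row[sel]
  }
  out
}

#' Continuous wavelet transform
#'
#' Frequency-domain CWT: one complex coefficient row per requested analysis
#' frequency, with per-scale L2 normalization (so \code{Mod(coef)^2} is
#' wavelet energy and scales with the square of signal amplitude).
#'
#' @param signal An \code{eeg_signal}.
#' @param wavelet A \code{wavelet_spec}.
#' @param frequencies Analysis frequencies in Hz, inside (0, rate/2).
#' @return Complex matrix, \code{length(frequencies)} x
#'   \code{length(signal)}.
#' @export
cwt <- function(signal, wavelet, frequencies) {
  stopifnot(inherits(signal, "eeg_signal"), inherits(wavelet, "wavelet_spec"))
  frequencies <- as.numeric(frequencies)
  if (any(frequencies <= 0 | frequencies >= signal$rate / 2))
    stop("frequencies must lie in (0, rate/2)")
  cwt_engine(signal$samples, signal$rate, wavelet, frequencies,
             reduce = "none")
}

#' Wavelet energy time series within a frequency band
#'
#' Mean of \code{Mod(cwt)^2} across a frequency grid spanning the band
#' (default 0.5 Hz spacing): the quantity thresholded by the spindle
#' detector.
#'
#' @param signal An \code{eeg_signal}.
#' @param wavelet A \code{wavelet_spec}.
#' @param band \code{c(lo, hi)} in Hz (default the 9-16 Hz spindle band).
#' @param step_hz Frequency-grid spacing in Hz (default 0.5).
#' @return \code{eeg_signal} holding the energy time series (uV^2).
#' @export
band_energy_series <- function(signal, wavelet, band = c(9, 16),
                               step_hz = 0.5, aggregate = c("mean", "max")) {
  stopifnot(inherits(signal, "eeg_signal"), inherits(wavelet, "wavelet_spec"))
  aggregate <- match.arg(aggregate)
  band <- check_band(band, signal$rate)
  freqs <- seq(band[1], band[2], by = step_hz)
  e <- cwt_engine(signal$samples, signal$rate, wavelet, freqs,
                  reduce = paste0(aggregate, "_energy"))
  eeg_signal(e, rate = signal$rate, label = paste0(signal$label, ".energy"),
             t0 = signal$t0)
}

#' Time-frequency representation (complex Morlet energy)
#'
#' \code{Mod(cwt)^2} with the complex Morlet wavelet, the spectrogram used
#' for visualizing spindles.
#'
#' @param signal An \code{eeg_signal}.
#' @param freq_grid Analysis frequencies in Hz.
#' @param wavelet Wavelet to use (default complex Morlet, fb = 1, fc = 1).
#' @return Real energy matrix, \code{length(freq_grid)} x
#'   \code{length(signal)}.
#' @export
tfr <- function(signal, freq_grid,
                wavelet = wavelet_spec("cmor", bandwidth_fb = 1,
                                       center_fc = 1)) {
  Mod(cwt(signal, wavelet, freq_grid))^2
}
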