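# The spindle detector: thresholded wavelet energy in the 9-16 Hz band with
# duration, cycle-count and band-specificity filters, plus per-event feature
# extraction (central frequency, cycles, peak-to-peak amplitude, symmetry).

#' Detection configuration
#'
#' Defaults follow the reference detection pipeline: wavelet energy in the
#' 9-16 Hz band smoothed with a 200 ms Hann window; candidates where energy
#' exceeds mean + 3 SD, expanded to the crossings of mean + 1 SD; events
#' shorter than 0.4 s or longer than 2 s discarded, as are events with fewer
#' than 5 or more than 30 cycles, and events whose power in the spindle band
#' is below either flanking band (6-8.5 or 16.5-20 Hz).
#'
#' @param band Spindle band \code{c(lo, hi)} in Hz.
#' @param smooth_ms Hann smoothing window (ms).
#' @param hi_sd,lo_sd Detection and boundary thresholds in baseline SD units;
#'   \code{hi_sd > lo_sd >= 0}.
#' @param min_dur_s,max_dur_s Duration bounds (s).
#' @param min_cycles,max_cycles Cycle-count bounds.
#' @param flank_lo,flank_hi Flanking bands for the specificity test (Hz).
#' @param wavelet \code{wavelet_spec}; default complex frequency B-spline
#'   (m = 2, fb = 1, fc = 1).
#' @param step_hz Frequency-grid spacing of the energy series (Hz).
#' @param baseline_scope \code{"NREM"} (baseline statistics over NREM samples
#'   when a hypnogram is given) or \code{"ALL"}.
#' @param fir_order_at_1k Order of the spindle-band FIR (at 1000 Hz).
#' @return Object of class \code{spindle_config}.
#' @export
spindle_config <- function(band = c(9, 16), smooth_ms = 200, hi_sd = 3,
                           lo_sd = 1, min_dur_s = 0.4, max_dur_s = 2.0,
                           min_cycles = 5, max_cycles = 30,
                           flank_lo = c(6, 8.5), flank_hi = c(16.5, 20),
                           wavelet = wavelet_spec("fbsp", order_m = 2,
                                                  bandwidth_fb = 0.5,
                                                  center_fc = 1),
                           step_hz = 0.5, baseline_scope = c("NREM", "ALL"),
                           fir_order_at_1k = 333) {
  baseline_scope <- match.arg(baseline_scope)
  if (!(hi_sd > lo_sd && lo_sd >= 0)) stop("need hi_sd > lo_sd >= 0")
  if (min_dur_s >= max_dur_s) stop("need min_dur_s < max_dur_s")
  if (min_cycles >= max_cycles) stop("need min_cycles < max_cycles")
  structure(list(band = band, smooth_ms = smooth_ms, hi_sd = hi_sd,
                 lo_sd = lo_sd, min_dur_s = min_dur_s, max_dur_s = max_dur_s,
                 min_cycles = min_cycles, max_cycles = max_cycles,
                 flank_lo = flank_lo, flank_hi = flank_hi, wavelet = wavelet,
                 step_hz = step_hz, baseline_scope = baseline_scope,
                 fir_order_at_1k = fir_order_at_1k),
            class = "spindle_config")
}

# symmetric same-length convolution with mirror padding
conv_same <- function(x, k) {
  n <- length(x); L <- length(k)
  half <- (L - 1L) %/% 2L
  pad <- min(n - 1L, L)
  xm <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  N <- next_fast_len(length(xm) + L)
  K <- stats::fft(c(k, rep(0, N - L)))
  X <- stats::fft(c(xm, rep(0, N - length(xm))))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / N
  y[(pad + half + 1L):(pad + half + n)]
}

#' Smooth an energy series with a unit-area Hann window
#'
#' @param energy An \code{eeg_signal} holding an energy time series.
#' @param smooth_ms Window length in ms (default 200).
#' @return Smoothed \code{eeg_signal}, same length.
#' @export
smooth_energy <- function(energy, smooth_ms = 200) {
  stopifnot(inherits(energy, "eeg_signal"))
  nk <- as.integer(round(smooth_ms / 1000 * energy$rate)) + 1L
  if (nk >= length(energy$samples)) stop("smoothing window longer than series")
  k <- hann_window(nk)
  k <- k / sum(k)
  eeg_signal(conv_same(energy$samples, k), rate = energy$rate,
             label = energy$label, t0 = energy$t0)
}

#' Dual-threshold interval extraction from a smoothed energy series
#'
#' Baseline mean and SD are computed over \code{baseline_mask} samples only.
#' A candidate exists wherever energy exceeds mean + \code{hi_sd} SD; each
#' candidate is expanded outward to the nearest crossings of mean +
#' \code{lo_sd} SD, and overlapping expanded intervals merge (equivalently:
#' the returned intervals are the maximal runs above the low threshold that
#' contain at least one sample above the high threshold).
#'
#' @param smoothed_energy An \code{eeg_signal} (smoothed energy).
#' @param baseline_mask Logical mask selecting baseline samples; NULL = all.
#' @param hi_sd,lo_sd Thresholds in SD units above the mean.
#' @return Data.frame of intervals (\code{start}, \code{end}, seconds), plus
#'   attributes \code{baseline_mean} and \code{baseline_sd}.
#' @export
threshold_events <- function(smoothed_energy, baseline_mask = NULL,
                             hi_sd = 3, lo_sd = 1) {
  stopifnot(inherits(smoothed_energy, "eeg_signal"))
  e <- smoothed_energy$samples
  if (is.null(baseline_mask)) baseline_mask <- rep(TRUE, length(e))
  if (!any(baseline_mask)) stop("empty baseline")
  mu <- mean(e[baseline_mask])
  sdv <- stats::sd(e[baseline_mask])
  out <- intervals()
  if (is.na(sdv) || sdv == 0) {
    warning("degenerate baseline (SD = 0); no events returned")
  } else {
    lo_thr <- mu + lo_sd * sdv
    hi_thr <- mu + hi_sd * sdv
    above_lo <- e > lo_thr
    r <- rle(above_lo)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    rows <- lapply(keep, function(i) {
      idx <- starts[i]:ends[i]
      if (any(e[idx] > hi_thr)) c(starts[i], ends[i]) else NULL
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      fs <- smoothed_energy$rate
      out <- intervals(start = smoothed_energy$t0 + (rows[, 1] - 1) / fs,
                       end = smoothed_energy$t0 + rows[, 2] / fs)
    }
  }
  attr(out, "baseline_mean") <- mu
  attr(out, "baseline_sd") <- if (exists("sdv")) sdv else NA_real_
  out
}

sample_range <- function(signal, start, end) {
  i0 <- max(1L, as.integer(floor((start - signal$t0) * signal$rate)) + 1L)
  i1 <- min(length(signal$samples),
            as.integer(ceiling((end - signal$t0) * signal$rate)))
  if (i1 < i0) i0:i0 else i0:i1
}

#' Count oscillation cycles within an event
#'
#' Number of positive local maxima of the band-pass filtered trace inside the
#' interval.
#'
#' @param filtered_signal The 9-16 Hz zero-phase filtered \code{eeg_signal}.
#' @param start,end Event bounds (s).
#' @return Integer cycle count.
#' @export
count_cycles <- function(filtered_signal, start, end) {
  stopifnot(inherits(filtered_signal, "eeg_signal"))
  idx <- sample_range(filtered_signal, start, end)
  x <- filtered_signal$samples[idx]
  if (length(x) < 3L) return(0L)
  i <- 2:(length(x) - 1L)
  sum(x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > 0)
}

#' Band-specificity test for a candidate event
#'
#' TRUE iff the modified-periodogram power of the raw trace over the event
#' extent is at least as large in the spindle band as in both flanking bands.
#'
#' @param signal Raw \code{eeg_signal}.
#' @param start,end Event bounds (s).
#' @param band Spindle band (Hz).
#' @param flank_lo,flank_hi Flanking bands (Hz).
#' @return Logical.
#' @export
band_specificity <- function(signal, start, end, band = c(9, 16),
                             flank_lo = c(6, 8.5), flank_hi = c(16.5, 20)) {
  stopifnot(inherits(signal, "eeg_signal"))
  x <- signal$samples[sample_range(signal, start, end)]
  p_mid <- bandpower(x, band, rate = signal$rate)
  p_lo <- bandpower(x, flank_lo, rate = signal$rate)
  p_hi <- bandpower(x, flank_hi, rate = signal$rate)
  p_mid >= p_lo && p_mid >= p_hi
}

#' Central frequency of an event via the Fourier transform
#'
#' Frequency of the amplitude-spectrum maximum within the search band of the
#' zero-padded (>= 8x length) de-meaned event segment.
#'
#' @param signal Raw \code{eeg_signal}.
#' @param start,end Event bounds (s).
#' @param band Search band (Hz), default 9-16.
#' @return Frequency in Hz.
#' @export
central_frequency <- function(signal, start, end, band = c(9, 16)) {
  stopifnot(inherits(signal, "eeg_signal"))
  x <- signal$samples[sample_range(signal, start, end)]
  x <- x - mean(x)
  N <- next_fast_len(max(8L * length(x),
                         as.integer(ceiling(signal$rate / 0.1))))
  X <- Mod(stats::fft(c(x, rep(0, N - length(x)))))
  freq <- (0:(N - 1)) * signal$rate / N
  sel <- which(freq >= band[1] & freq <= band[2])
  freq[sel[which.max(X[sel])]]
}

#' Symmetry index of an event
#'
#' Position of the smoothed wavelet-energy peak relative to the event bounds:
#' \code{(t_peak - start) / (end - start)}, in \[0, 1\]. 0.5 is complete
#' symmetry; lower/higher values indicate a leftward/rightward energy peak.
#'
#' @param smoothed_energy Smoothed energy \code{eeg_signal}.
#' @param start,end Event bounds (s).
#' @return Symmetry in \[0, 1\] (also returns the peak time as attribute
#'   \code{peak_t}).
#' @export
spindle_symmetry <- function(smoothed_energy, start, end) {
  stopifnot(inherits(smoothed_energy, "eeg_signal"), end > start)
  idx <- sample_range(smoothed_energy, start, end)
  rel <- which.max(smoothed_energy$samples[idx])
  t_peak <- smoothed_energy$t0 + (idx[rel] - 1L) / smoothed_energy$rate
  out <- (t_peak - start) / (end - start)
  out <- min(1, max(0, out))
  attr(out, "peak_t") <- t_peak
  out
}

#' Vigilance state of an event
#'
#' The state with the largest temporal overlap with the event; exact ties are
#' broken by the state at the event midpoint.
#'
#' @param start,end Event bounds (s).
#' @param hyp A \code{hypnogram} covering the event.
#' @return One of \code{"WAKE"}, \code{"NREM"}, \code{"REM"}.
#' @export
assign_state <- function(start, end, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (start < 0 || end > hypnogram_duration(hyp))
    stop("event outside hypnogram span")
  k0 <- floor(start / hyp$epoch_s)
  k1 <- ceiling(end / hyp$epoch_s) - 1
  ov <- stats::setNames(numeric(3), VIGILANCE_STATES)
  for (k in k0:k1) {
    lo <- max(start, k * hyp$epoch_s)
    hi <- min(end, (k + 1) * hyp$epoch_s)
    st <- hyp$labels[k + 1]
    ov[st] <- ov[st] + (hi - lo)
  }
  best <- names(ov)[ov == max(ov)]
  if (length(best) > 1L) state_at(hyp, (start + end) / 2) else best
}

#' Detect sleep spindles
#'
#' Full detection pipeline: wavelet band-energy series (9-16 Hz, complex
#' frequency B-spline) -> 200 ms Hann smoothing -> dual-threshold interval
#' extraction (mean + 3 SD detection, mean + 1 SD boundaries) -> duration
#' filter (0.4-2 s) -> cycle filter (5-30 positive peaks of the band-passed
#' trace) -> band-specificity filter -> feature extraction -> state labeling.
#' Thresholds are data-relative, so detection is invariant to global
#' amplitude rescaling.
#'
#' @param signal Raw \code{eeg_signal} (rate >= 100 Hz).
#' @param config A \code{spindle_config}.
#' @param hyp Optional \code{hypnogram}; when supplied, baseline statistics
#'   are restricted to NREM samples (if \code{baseline_scope == "NREM"}) and
#'   events get state labels.
#' @return Object of class \code{spindle_detection} with elements
#'   \code{events} (data.frame: start_s, end_s, channel, state, freq_hz,
#'   n_cycles, p2p_uv, symmetry, energy_peak_t), \code{config},
#'   \code{baseline} (mean, sd), \code{n_candidates} and \code{signal_info}.
#' @examples
#' \donttest{
#' cfg <- synth_config(duration_min = 3, seed = 1)
#' rec <- generate_recording(cfg)
#' det <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
#' summary(det)
#' }
#' @export
detect_spindles <- function(signal, config = spindle_config(), hyp = NULL) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (signal$rate < 100) stop("signal rate must be >= 100 Hz")
  energy <- band_energy_series(signal, config$wavelet, config$band,
                               config$step_hz)
  sm <- smooth_energy(energy, config$smooth_ms)
  mask <- NULL
  if (!is.null(hyp) && config$baseline_scope == "NREM") {
    mask <- state_mask(hyp, "NREM", signal$rate, length(signal$samples))
    if (!any(mask)) mask <- NULL   # no NREM scored: fall back to full trace
  }
  cand <- threshold_events(sm, mask, config$hi_sd, config$lo_sd)
  bl_mean <- attr(cand, "baseline_mean")
  bl_sd <- attr(cand, "baseline_sd")
  n_cand <- nrow(cand)
  dur <- cand$end - cand$start
  cand <- cand[dur >= config$min_dur_s & dur <= config$max_dur_s, ,
               drop = FALSE]
  filt <- fir_bandpass(signal, config$band,
                       order_at_1k = config$fir_order_at_1k)
  rows <- vector("list", nrow(cand))
  hyp_end <- if (!is.null(hyp)) hypnogram_duration(hyp) else Inf
  for (i in seq_len(nrow(cand))) {
    s0 <- cand$start[i]; s1 <- cand$end[i]
    nc <- count_cycles(filt, s0, s1)
    if (nc < config$min_cycles || nc > config$max_cycles) next
    if (!band_specificity(signal, s0, s1, config$band, config$flank_lo,
                          config$flank_hi)) next
    sym <- spindle_symmetry(sm, s0, s1)
    seg <- filt$samples[sample_range(filt, s0, s1)]
    st <- if (!is.null(hyp) && s0 >= 0 && s1 <= hyp_end)
      assign_state(s0, s1, hyp) else NA_character_
    rows[[i]] <- data.frame(
      start_s = s0, end_s = s1, channel = signal$label, state = st,
      freq_hz = central_frequency(signal, s0, s1, config$band),
      n_cycles = nc, p2p_uv = max(seg) - min(seg),
      symmetry = as.numeric(sym), energy_peak_t = attr(sym, "peak_t"),
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, rows)
  if (is.null(events))
    events <- data.frame(start_s = numeric(), end_s = numeric(),
                         channel = character(), state = character(),
                         freq_hz = numeric(), n_cycles = integer(),
                         p2p_uv = numeric(), symmetry = numeric(),
                         energy_peak_t = numeric(), stringsAsFactors = FALSE)
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, config = config,
                 baseline = c(mean = bl_mean, sd = bl_sd),
                 n_candidates = n_cand,
                 signal_info = list(label = signal$label, rate = signal$rate,
                                    duration_s = signal_duration(signal))),
            class = "spindle_detection")
}

#' @export
print.spindle_detection <- function(x, ...) {
  cat(sprintf("<spindle_detection> %d events on '%s' (%.1f min @ %g Hz)\n",
              nrow(x$events), x$signal_info$label,
              x$signal_info$duration_s / 60, x$signal_info$rate))
  invisible(x)
}

#' @export
summary.spindle_detection <- function(object, ...) {
  ev <- object$events
  cat(sprintf("Spindle detection on '%s': %.1f min at %g Hz\n",
              object$signal_info$label, object$signal_info$duration_s / 60,
              object$signal_info$rate))
  cat(sprintf("  candidates above threshold: %d; retained events: %d\n",
              object$n_candidates, nrow(ev)))
  cat(sprintf("  baseline energy: mean %.3g, SD %.3g uV^2\n",
              object$baseline[["mean"]], object$baseline[["sd"]]))
  if (nrow(ev) > 0) {
    cat(sprintf("  duration: %.2f +/- %.2f s; central frequency: %.1f +/- %.1f Hz\n",
                mean(ev$end_s - ev$start_s), stats::sd(ev$end_s - ev$start_s),
                mean(ev$freq_hz), stats::sd(ev$freq_hz)))
    cat(sprintf("  cycles: %.1f +/- %.1f; symmetry: %.2f +/- %.2f\n",
                mean(ev$n_cycles), stats::sd(ev$n_cycles),
                mean(ev$symmetry), stats::sd(ev$symmetry)))
    if (!all(is.na(ev$state))) {
      tab <- table(ev$state)
      cat("  events by state:",
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
  }
  invisible(object)
}

#' @export
as.data.frame.spindle_detection <- function(x, ...) x$events

#' Plot detected spindles over the raw trace
#' @param x A \code{spindle_detection}.
#' @param signal The raw \code{eeg_signal} that was analyzed.
#' @param window Optional \code{c(t0, t1)} view window in seconds.
#' @param ... Passed to \code{plot}.
#' @export
plot.spindle_detection <- function(x, signal, window = NULL, ...) {
  stopifnot(inherits(signal, "eeg_signal"))
  t <- signal_times(signal)
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  graphics::plot(t[sel], signal$samples[sel], type = "l", col = "grey30",
                 xlab = "time (s)", ylab = "amplitude (uV)", ...)
  ev <- x$events
  ev <- ev[ev$end_s >= window[1] & ev$start_s <= window[2], , drop = FALSE]
  if (nrow(ev) > 0)
    graphics::rect(ev$start_s, min(signal$samples[sel]), ev$end_s,
                   max(signal$samples[sel]),
                   col = grDevices::adjustcolor("firebrick", 0.2),
                   border = NA)
  invisible(x)
}

#' Match detected events against ground-truth intervals
#'
#' Greedy one-to-one matching in time order: a detected event matches a truth
#' interval when their intersection covers at least \code{min_overlap} of the
#' shorter of the two intervals.
#'
#' @param detected Data.frame with \code{start_s}, \code{end_s} (or a
#'   \code{spindle_detection}).
#' @param truth Data.frame with \code{start}, \code{end}.
#' @param min_overlap Required overlap fraction of the shorter interval.
#' @return List with \code{n_detected}, \code{n_truth}, \code{n_matched},
#'   \code{sensitivity} (matched / truth) and \code{fdr}
#'   (unmatched detections / detections).
#' @export
detection_performance <- function(detected, truth, min_overlap = 0.5) {
  if (inherits(detected, "spindle_detection")) detected <- detected$events
  nd <- nrow(detected); nt <- nrow(truth)
  used <- rep(FALSE, nt)
  matched <- 0L
  for (i in seq_len(nd)) {
    a0 <- detected$start_s[i]; a1 <- detected$end_s[i]
    for (j in seq_len(nt)) {
      if (used[j]) next
      ov <- min(a1, truth$end[j]) - max(a0, truth$start[j])
      shorter <- min(a1 - a0, truth$end[j] - truth$start[j])
      if (ov >= min_overlap * shorter) {
        used[j] <- TRUE
        matched <- matched + 1L
        break
      }
    }
  }
  list(n_detected = nd, n_truth = nt, n_matched = matched,
       sensitivity = if (nt > 0) matched / nt else NA_real_,
       fdr = if (nd > 0) (nd - matched) / nd else NA_real_)
}
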