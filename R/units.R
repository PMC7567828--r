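# Spike-level analyses: threshold spike detection, burst detection,
# firing-rate curves, spike-field coupling, SW-spindle coupling, UP-state
# detection and coincidence, delta power during spindles and firing-rate
# modulation.

#' Construct a spike train
#' @param times Strictly increasing, nonnegative spike times (s).
#' @param unit_id Unit name.
#' @param source_channel Channel the unit was recorded on.
#' @return Object of class \code{spike_train}.
#' @export
spike_train <- function(times, unit_id = "u1", source_channel = NA_character_) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("spike times must be nonnegative")
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  structure(list(times = times, unit_id = unit_id,
                 source_channel = source_channel), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes%s\n", x$unit_id, length(x$times),
              if (length(x$times)) sprintf(" over %.1f s", diff(range(x$times)))
              else ""))
  invisible(x)
}

spike_times_of <- function(train) {
  if (inherits(train, "spike_train")) train$times else as.numeric(train)
}

#' Detect spikes from a wideband trace
#'
#' Zero-phase elliptic band-pass (order 4, 0.1 dB passband ripple, 40 dB
#' stopband, 600-4000 Hz), then an amplitude threshold of 7.5 times the
#' median absolute filtered value. Crossings of either polarity are grouped
#' within a 1-ms refractory window and each spike is timed at the extremum of
#' the group.
#'
#' @param signal Wideband \code{eeg_signal}, rate >= 10 kHz.
#' @param band Band edges in Hz (default 600-4000).
#' @param threshold_mult Threshold multiplier on median(|filtered|)
#'   (default 7.5).
#' @param refractory_ms Grouping window in ms (default 1).
#' @param unit_id Name assigned to the resulting train.
#' @return A \code{spike_train}; empty (with a warning) for a flat trace.
#' @export
detect_spikes <- function(signal, band = c(600, 4000), threshold_mult = 7.5,
                          refractory_ms = 1, unit_id = "u1") {
  stopifnot(inherits(signal, "eeg_signal"))
  if (signal$rate < 10000) stop("spike detection requires rate >= 10 kHz")
  band <- check_band(band, signal$rate)
  flt <- signal::ellip(4, 0.1, 40, band / (signal$rate / 2), "pass")
  x <- as.numeric(signal::filtfilt(flt, signal$samples))
  thr <- threshold_mult * stats::median(abs(x))
  if (thr == 0) {
    warning("flat filtered trace: no spikes detectable")
    return(spike_train(numeric(0), unit_id, signal$label))
  }
  over <- which(abs(x) > thr)
  if (length(over) == 0L)
    return(spike_train(numeric(0), unit_id, signal$label))
  refr <- max(1L, as.integer(round(refractory_ms / 1000 * signal$rate)))
  brk <- c(0L, which(diff(over) > refr), length(over))
  times <- numeric(length(brk) - 1L)
  for (g in seq_len(length(brk) - 1L)) {
    idx <- over[(brk[g] + 1L):brk[g + 1L]]
    peak <- idx[which.max(abs(x[idx]))]
    times[g] <- (peak - 1L) / signal$rate
  }
  spike_train(times, unit_id, signal$label)
}

#' Detect burst firing in a spike train
#'
#' A burst is a maximal run of at least \code{min_spikes} spikes whose
#' inter-spike intervals are all below \code{max_isi_ms}, preceded by a
#' quiescent period of at least \code{quiescence_ms} (or starting the train).
#'
#' @param train A \code{spike_train} or numeric spike-time vector (s).
#' @param max_isi_ms Intra-burst ISI bound in ms (default 6, exclusive).
#' @param min_spikes Minimum spikes per burst (default 3).
#' @param quiescence_ms Minimum preceding silence in ms (default 50).
#' @return Data.frame with \code{start_s}, \code{n_spikes}, \code{unit}; zero
#'   rows when no burst qualifies.
#' @examples
#' detect_bursts(c(0.9, 1.0, 1.004, 1.008))
#' @export
detect_bursts <- function(train, max_isi_ms = 6, min_spikes = 3,
                          quiescence_ms = 50) {
  t <- spike_times_of(train)
  unit <- if (inherits(train, "spike_train")) train$unit_id else "u1"
  empty <- data.frame(start_s = numeric(0), n_spikes = integer(0),
                      unit = character(0), stringsAsFactors = FALSE)
  n <- length(t)
  if (n < min_spikes) return(empty)
  isi <- diff(t) * 1000
  fast <- isi < max_isi_ms
  # maximal runs of consecutive fast ISIs
  r <- rle(fast)
  pos <- cumsum(c(1L, r$lengths))
  out <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- pos[k]                      # first spike of the run
    len <- r$lengths[k] + 1L          # spikes in the run
    if (len < min_spikes) next
    if (i0 > 1L && (t[i0] - t[i0 - 1L]) * 1000 < quiescence_ms) next
    out[[length(out) + 1L]] <- data.frame(start_s = t[i0],
                                          n_spikes = len, unit = unit,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Trial-averaged firing-rate curve
#'
#' Bins each trial's spikes with a moving window (default 10 ms long, 8 ms
#' overlap, i.e. 2-ms steps) and averages the resulting rate traces across
#' trials.
#'
#' @param trials List of numeric spike-time vectors, each aligned to a common
#'   zero.
#' @param t_range \code{c(t0, t1)}: the common analysis frame (s).
#' @param window_ms,overlap_ms Window length and overlap in ms.
#' @return List with \code{t} (window centers, s), \code{rate} (mean rate,
#'   Hz), \code{n_trials}, \code{step_ms}.
#' @export
rate_curve <- function(trials, t_range, window_ms = 10, overlap_ms = 8) {
  if (!is.list(trials) || length(trials) == 0L) stop("empty trial set")
  if (overlap_ms >= window_ms) stop("need overlap_ms < window_ms")
  w <- window_ms / 1000
  step <- (window_ms - overlap_ms) / 1000
  if (diff(t_range) < w) stop("t_range shorter than one window")
  centers <- seq(t_range[1] + w / 2, t_range[2] - w / 2, by = step)
  acc <- numeric(length(centers))
  for (tr in trials) {
    tr <- as.numeric(tr)
    # 1-ns tolerance so boundary spikes land in exactly one window despite
    # floating-point center arithmetic
    cnt <- vapply(centers, function(cc)
      sum(tr - (cc - w / 2) >= -1e-9 & tr - (cc + w / 2) < -1e-9), numeric(1))
    acc <- acc + cnt / w
  }
  list(t = centers, rate = acc / length(trials), n_trials = length(trials),
       step_ms = window_ms - overlap_ms)
}

#' Central peak of a filtered trace within an event
#'
#' The local maximum of the band-passed signal closest to the event midpoint
#' (the spindle's central peak); equidistant ties resolve to the earlier
#' peak.
#'
#' @param filtered_signal Band-passed \code{eeg_signal} (9-16 Hz for
#'   spindles).
#' @param event List or one-row data.frame with \code{start_s} and
#'   \code{end_s} (or \code{start}/\code{end}).
#' @return Peak time in seconds.
#' @export
central_peak <- function(filtered_signal, event) {
  stopifnot(inherits(filtered_signal, "eeg_signal"))
  t0 <- if (!is.null(event$start_s)) event$start_s else event$start
  t1 <- if (!is.null(event$end_s)) event$end_s else event$end
  idx <- sample_range(filtered_signal, t0, t1)
  x <- filtered_signal$samples
  cand <- idx[idx > 1L & idx < length(x)]
  pk <- cand[x[cand] > x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (length(pk) == 0L) stop("no local maximum inside event")
  tpk <- (pk - 1L) / filtered_signal$rate
  mid <- (t0 + t1) / 2
  d <- abs(tpk - mid)
  tpk[which.min(d)]   # which.min takes the first (earlier) on exact ties
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> value %.3f at lag %+.1f ms (n = %d events)\n",
              x$value, x$lag_ms, x$n_events))
  invisible(x)
}

coupling_result <- function(value, lag_ms, n_events) {
  structure(list(value = value, lag_ms = lag_ms, n_events = n_events),
            class = "coupling_result")
}

#' Spike-field coupling during spindles
#'
#' For every spindle, extracts a window (default +/-250 ms) of the 9-16 Hz
#' filtered LFP around the spindle's central peak together with the spikes in
#' the same frame; averages the LFP and the firing-rate curve across
#' spindles; and reports the peak normalized cross-correlation between the
#' two averages within \code{max_lag_ms}. Positive lag means the spikes
#' follow the LFP peak.
#'
#' @param lfp An \code{eeg_signal}.
#' @param train A \code{spike_train} (times co-registered with the LFP).
#' @param spindles Data.frame of events with \code{start_s}, \code{end_s}.
#' @param max_lag_ms Lag search range (default 100 ms).
#' @param window_ms Half window around the central peak (default 250 ms).
#' @param band Field band in Hz (default 9-16).
#' @param fir_order_at_1k Field filter order at 1000 Hz (default 333).
#' @param filtered_field Optional precomputed band-passed LFP
#'   (\code{eeg_signal}); avoids refiltering when coupling several trains
#'   against the same recording.
#' @return A \code{coupling_result} (\code{value}, \code{lag_ms},
#'   \code{n_events}).
#' @export
spike_field_coupling <- function(lfp, train, spindles, max_lag_ms = 100,
                                 window_ms = 250, band = c(9, 16),
                                 fir_order_at_1k = 333,
                                 filtered_field = NULL) {
  stopifnot(inherits(lfp, "eeg_signal"))
  if (is.null(spindles) || nrow(spindles) == 0L) stop("no spindles given")
  tsp <- spike_times_of(train)
  filt <- if (is.null(filtered_field))
    fir_bandpass(lfp, band, order_at_1k = fir_order_at_1k)
  else filtered_field
  half <- window_ms / 1000
  nh <- as.integer(round(half * lfp$rate))
  total_s <- signal_duration(lfp)
  acc <- numeric(2L * nh + 1L)
  trials <- list()
  n_used <- 0L
  for (i in seq_len(nrow(spindles))) {
    cp <- central_peak(filt, spindles[i, ])
    ci <- as.integer(round(cp * lfp$rate)) + 1L
    if (ci - nh < 1L || ci + nh > length(filt$samples)) next
    n_used <- n_used + 1L
    acc <- acc + filt$samples[(ci - nh):(ci + nh)]
    trials[[n_used]] <- tsp[tsp >= cp - half & tsp <= cp + half] - cp
  }
  if (n_used == 0L) stop("no spindle window fits inside the recording")
  avg_lfp <- acc / n_used
  rc <- rate_curve(trials, c(-half, half))
  if (all(rc$rate == 0)) stop("no spikes in any peri-event window")
  # sample the averaged LFP on the rate-curve grid
  li <- as.integer(round((rc$t + half) * lfp$rate)) + 1L
  grid_rate <- 1000 / rc$step_ms
  xc <- normalized_xcorr(avg_lfp[li], rc$rate,
                         max_lag = as.integer(round(max_lag_ms / rc$step_ms)),
                         rate = grid_rate)
  coupling_result(xc$peak, xc$peak_lag_ms, n_used)
}

#' Slow-wave / spindle-envelope coupling
#'
#' Aligns the 0.5-4 Hz filtered trace and the Hilbert envelope of the 9-16 Hz
#' trace to spindle onsets (window -1 to +2 s), averages each across
#' spindles, and reports the peak normalized cross-correlation within
#' \code{max_lag_ms}. Positive lag means the envelope trails the slow wave.
#'
#' @param lfp An \code{eeg_signal}.
#' @param spindles Data.frame with \code{start_s}, \code{end_s}.
#' @param max_lag_ms Lag search range (default 500 ms).
#' @param pre_s,post_s Window around onset in s (defaults 1 and 2).
#' @param sw_band,sw_order_at_1k Slow-wave band and filter order at 1000 Hz.
#' @param band Spindle band for the envelope.
#' @return A \code{coupling_result}.
#' @export
sw_spindle_coupling <- function(lfp, spindles, max_lag_ms = 500, pre_s = 1,
                                post_s = 2, sw_band = c(0.5, 4),
                                sw_order_at_1k = 6000, band = c(9, 16)) {
  stopifnot(inherits(lfp, "eeg_signal"))
  if (is.null(spindles) || nrow(spindles) == 0L) stop("no spindles given")
  sw <- fir_bandpass(lfp, sw_band, order_at_1k = sw_order_at_1k)
  env <- hilbert_envelope(fir_bandpass(lfp, band, order_at_1k = 333))
  npre <- as.integer(round(pre_s * lfp$rate))
  npost <- as.integer(round(post_s * lfp$rate))
  acc_sw <- numeric(npre + npost + 1L)
  acc_env <- numeric(npre + npost + 1L)
  n_used <- 0L
  for (i in seq_len(nrow(spindles))) {
    oi <- as.integer(round(spindles$start_s[i] * lfp$rate)) + 1L
    if (oi - npre < 1L || oi + npost > length(sw$samples)) next
    n_used <- n_used + 1L
    sel <- (oi - npre):(oi + npost)
    acc_sw <- acc_sw + sw$samples[sel]
    acc_env <- acc_env + env$samples[sel]
  }
  if (n_used == 0L) stop("no spindle window fits inside the recording")
  xc <- normalized_xcorr(acc_sw / n_used, acc_env / n_used,
                         max_lag = as.integer(round(max_lag_ms / 1000 *
                                                      lfp$rate)),
                         rate = lfp$rate)
  coupling_result(xc$peak, xc$peak_lag_ms, n_used)
}

#' Detect UP states from the slow-wave band
#'
#' Band-passes the signal to 0.5-4 Hz and takes the positive half-waves
#' (segments between a negative-to-positive and the following
#' positive-to-negative zero crossing); half-waves shorter than 200 ms or
#' whose peak amplitude is below the mean absolute filtered amplitude are
#' discarded.
#'
#' @param signal An \code{eeg_signal}.
#' @param min_dur_s Minimum half-wave duration (default 0.2 s).
#' @param band Slow-wave band in Hz.
#' @param order,order_at_1k Filter order (one of the two; default order 6000
#'   at 1000 Hz, the slow-wave reference order).
#' @param sign Set \code{-1} when the recording's polarity makes UP states
#'   negative deflections.
#' @return Data.frame with \code{start_s}, \code{end_s}, \code{peak_uv}.
#' @export
detect_up_states <- function(signal, min_dur_s = 0.2, band = c(0.5, 4),
                             order = NULL, order_at_1k = 6000, sign = 1) {
  stopifnot(inherits(signal, "eeg_signal"))
  filt <- fir_bandpass(signal, band, order = order,
                       order_at_1k = if (is.null(order)) order_at_1k else NULL)
  x <- sign * filt$samples
  amp_floor <- mean(abs(x))
  pos <- x > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- (i1 - i0 + 1L) / signal$rate
    pk <- max(x[i0:i1])
    if (dur >= min_dur_s && pk >= amp_floor)
      out[[length(out) + 1L]] <- data.frame(start_s = (i0 - 1L) / signal$rate,
                                            end_s = i1 / signal$rate,
                                            peak_uv = pk)
  }
  if (length(out) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_uv = numeric(0)))
  do.call(rbind, out)
}

event_bounds <- function(df) {
  s <- if (!is.null(df$start_s)) df$start_s else df$start
  e <- if (!is.null(df$end_s)) df$end_s else df$end
  list(start = s, end = e)
}

#' Fraction of spindles coinciding with UP states
#'
#' A spindle coincides with UP states when its overlap with the union of UP
#' intervals is at least half the spindle's duration.
#'
#' @param spindles Data.frame with \code{start_s}/\code{end_s} (or
#'   \code{start}/\code{end}).
#' @param up_states Data.frame of UP intervals (same column convention).
#' @return Ratio in [0, 1].
#' @export
spindle_up_coincidence <- function(spindles, up_states) {
  if (is.null(spindles) || nrow(spindles) == 0L) stop("empty spindle list")
  sp <- event_bounds(spindles)
  up <- if (is.null(up_states) || nrow(up_states) == 0L)
    list(start = numeric(0), end = numeric(0)) else event_bounds(up_states)
  hit <- vapply(seq_along(sp$start), function(i) {
    ov <- sum(pmax(0, pmin(sp$end[i], up$end) - pmax(sp$start[i], up$start)))
    ov >= 0.5 * (sp$end[i] - sp$start[i])
  }, logical(1))
  mean(hit)
}

#' Mean delta power during spindles
#'
#' Band power in 0.5-4 Hz of a 4-s Hann-windowed segment centered on each
#' spindle midpoint, averaged over spindles. Spindles whose window exceeds
#' the recording bounds are dropped with a warning.
#'
#' @param signal An \code{eeg_signal}.
#' @param spindles Data.frame with \code{start_s}, \code{end_s}.
#' @param band Delta band in Hz (default 0.5-4).
#' @param window_s Centered window length (default 4 s).
#' @return Mean power in uV^2.
#' @export
delta_power_during_spindles <- function(signal, spindles, band = c(0.5, 4),
                                        window_s = 4) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (is.null(spindles) || nrow(spindles) == 0L) stop("no spindles given")
  nw <- as.integer(round(window_s * signal$rate))
  n <- length(signal$samples)
  vals <- numeric(0)
  dropped <- 0L
  for (i in seq_len(nrow(spindles))) {
    mid <- (spindles$start_s[i] + spindles$end_s[i]) / 2
    i0 <- as.integer(round((mid - window_s / 2) * signal$rate)) + 1L
    if (i0 < 1L || i0 + nw - 1L > n) { dropped <- dropped + 1L; next }
    vals <- c(vals, bandpower(signal$samples[i0:(i0 + nw - 1L)], band,
                              rate = signal$rate))
  }
  if (dropped > 0L)
    warning(dropped, " spindle window(s) exceeded recording bounds; dropped")
  if (length(vals) == 0L) stop("no spindle window fits inside the recording")
  mean(vals)
}

total_interval_s <- function(iv) {
  b <- event_bounds(iv)
  sum(b$end - b$start)
}

count_in_intervals <- function(t, iv) {
  b <- event_bounds(iv)
  sum(vapply(t, function(tt) any(tt >= b$start & tt < b$end), logical(1)))
}

#' Firing-rate modulation between condition masks
#'
#' Ratio of spike rate (and of burst-event rate) between two disjoint
#' interval sets, e.g. inside vs outside spindles.
#'
#' @param train A \code{spike_train} or numeric spike times (s).
#' @param on_intervals,off_intervals Data.frames of intervals
#'   (\code{start_s}/\code{end_s} or \code{start}/\code{end}), each with
#'   positive total duration.
#' @return List with \code{unit_ratio}, \code{burst_ratio} (on/off;
#'   \code{NA} with a warning when the off rate is zero) plus the four
#'   underlying rates in Hz.
#' @export
rate_modulation <- function(train, on_intervals, off_intervals) {
  t <- spike_times_of(train)
  d_on <- total_interval_s(on_intervals)
  d_off <- total_interval_s(off_intervals)
  if (d_on <= 0 || d_off <= 0) stop("interval sets must have positive duration")
  if (length(t) == 0L)
    return(list(unit_ratio = 0, burst_ratio = 0, spike_rate_on = 0,
                spike_rate_off = 0, burst_rate_on = 0, burst_rate_off = 0))
  bursts <- detect_bursts(t)
  s_on <- count_in_intervals(t, on_intervals) / d_on
  s_off <- count_in_intervals(t, off_intervals) / d_off
  b_on <- count_in_intervals(bursts$start_s, on_intervals) / d_on
  b_off <- count_in_intervals(bursts$start_s, off_intervals) / d_off
  ratio <- function(on, off, what) {
    if (off == 0) {
      if (on > 0) warning("zero off-rate: ", what, " ratio undefined")
      if (on > 0) NA_real_ else 0
    } else on / off
  }
  list(unit_ratio = ratio(s_on, s_off, "unit"),
       burst_ratio = ratio(b_on, b_off, "burst"),
       spike_rate_on = s_on, spike_rate_off = s_off,
       burst_rate_on = b_on, burst_rate_off = b_off)
}
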