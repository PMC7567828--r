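# Synthetic polysomnography generator: state-structured LFP/EMG with NREM
# slow waves, waxing-waning spindles, wake/REM theta, 1/f background, and
# spike trains phase-locked to spindle cycles -- all with ground truth, so
# every analysis stage can be validated against known parameters.

#' Configuration for the synthetic recording generator
#'
#' Defaults emulate a freely behaving mouse: alternating Wake/NREM/REM bouts
#' (REM entered only from NREM), 3 spindles per NREM minute with central
#' frequencies clustered near 11.5 Hz, a 3x spindle-rate boost in the final
#' 25 s before REM onset, NREM slow waves (0.5-4 Hz), wake/REM theta
#' (6-10 Hz), a 1/f background, and state-scaled EMG tone.
#'
#' Spindle amplitude is specified as SNR: the ratio of the spindle's peak
#' envelope to the SD of the 9-16 Hz filtered NREM background (measured on
#' the spindle-free composite background during generation).
#'
#' @param seed Integer seed; all draws derive from it.
#' @param duration_min Recording length in minutes.
#' @param rate Sampling rate in Hz (default 1000).
#' @param wake_mean_s,wake_min_s,nrem_mean_s,nrem_min_s,rem_mean_s,rem_min_s
#'   Bout-duration model: exponential means with hard floors (s).
#' @param p_nrem_to_rem Probability that a NREM bout ends in REM (else wake).
#' @param sw_amplitude_uv SD of the NREM slow-wave (0.5-4 Hz) component.
#' @param spindle_rate_per_min Base NREM spindle rate (min^-1).
#' @param spindle_freq_mean_hz,spindle_freq_sd_hz,spindle_freq_range_hz
#'   Central-frequency model: truncated normal (Hz).
#' @param spindle_dur_range_s Event duration range (s), drawn uniformly.
#' @param spindle_snr Peak envelope / NREM sigma-band background SD.
#' @param spindle_asym_range Range of envelope peak positions (fraction of
#'   event duration), exercising the symmetry feature.
#' @param pre_rem_boost Spindle-intensity multiplier in the pre-REM window.
#' @param pre_rem_window_s Length of the boosted window before REM onset (s).
#' @param sw_lock If TRUE, spindle centers snap to the nearest positive peak
#'   of the slow-wave component (maximal SW-spindle coupling).
#' @param theta_amplitude_uv SD of the wake/REM theta (6-10 Hz) component.
#' @param noise_exponent,noise_scale_uv 1/f^exponent background and its SD.
#' @param emg_scale_uv EMG noise SD during wake (scaled 0.2/0.05 in
#'   NREM/REM).
#' @param spike_rate_hz Baseline firing rate of the generated unit.
#' @param spike_kappa Spindle-phase coupling strength in \[0, 1\].
#' @param spike_lag_ms Lag of spiking behind the LFP spindle peak (ms).
#' @param burst_p Probability that a spike is replaced by a 3-spike burst.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L, duration_min = 10, rate = 1000,
                         wake_mean_s = 60, wake_min_s = 20,
                         nrem_mean_s = 150, nrem_min_s = 30,
                         rem_mean_s = 60, rem_min_s = 15,
                         p_nrem_to_rem = 0.4,
                         sw_amplitude_uv = 100,
                         spindle_rate_per_min = 3,
                         spindle_freq_mean_hz = 11.5,
                         spindle_freq_sd_hz = 1.2,
                         spindle_freq_range_hz = c(9, 16),
                         spindle_dur_range_s = c(0.4, 1.5),
                         spindle_snr = 5,
                         spindle_asym_range = c(0.3, 0.7),
                         pre_rem_boost = 3, pre_rem_window_s = 25,
                         sw_lock = FALSE,
                         theta_amplitude_uv = 40,
                         noise_exponent = 1, noise_scale_uv = 30,
                         emg_scale_uv = 50,
                         spike_rate_hz = 8, spike_kappa = 0.6,
                         spike_lag_ms = 0, burst_p = 0.1) {
  stopifnot(duration_min > 0, rate > 0,
            spike_kappa >= 0, spike_kappa <= 1,
            p_nrem_to_rem >= 0, p_nrem_to_rem <= 1,
            pre_rem_boost >= 0, pre_rem_window_s > 0,
            spindle_rate_per_min > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> %.0f min @ %g Hz, seed %d\n",
                     "  spindles: %.1f/min NREM, SNR %.1f, boost %.1fx in %g s pre-REM\n"),
              x$duration_min, x$rate, x$seed, x$spindle_rate_per_min,
              x$spindle_snr, x$pre_rem_boost, x$pre_rem_window_s))
  invisible(x)
}

# run expr under set.seed(seed) (NULL = continue the current stream),
# restoring the caller's RNG state afterwards
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  eval.parent(substitute(expr))
}

#' Generate a state-structured hypnogram
#'
#' Alternating-bout semi-Markov chain: Wake -> NREM; NREM -> REM with
#' probability \code{p_nrem_to_rem}, else wake; REM -> wake. Bout durations
#' are exponential with a floor, rounded to whole 1-s epochs. Deterministic
#' given the seed.
#'
#' @param config A \code{synth_config}.
#' @param seed Seed (default \code{config$seed}); NULL continues the current
#'   RNG stream.
#' @return A \code{hypnogram} of \code{duration_min} minutes.
#' @export
generate_hypnogram <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(seed, {
    total <- config$duration_min * 60
    labels <- character(0)
    state <- "WAKE"
    while (length(labels) < total) {
      par <- switch(state,
        WAKE = c(config$wake_mean_s, config$wake_min_s),
        NREM = c(config$nrem_mean_s, config$nrem_min_s),
        REM = c(config$rem_mean_s, config$rem_min_s))
      dur <- max(1, round(par[2] + stats::rexp(1, 1 / max(par[1] - par[2], 1))))
      labels <- c(labels, rep(state, dur))
      state <- switch(state,
        WAKE = "NREM",
        NREM = if (stats::runif(1) < config$p_nrem_to_rem) "REM" else "WAKE",
        REM = "WAKE")
    }
    hypnogram(labels[seq_len(total)], epoch_s = 1)
  })
}

# 1/f^alpha gaussian noise of length n, unit SD
pink_noise <- function(n, alpha) {
  N <- next_fast_len(n)
  k <- 0:(N - 1)
  f <- pmin(k, N - k)
  shape <- c(0, (f[-1])^(-alpha / 2))
  ph <- stats::rnorm(N) + 1i * stats::rnorm(N)
  x <- Re(stats::fft(ph * shape, inverse = TRUE))
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# gaussian noise band-limited to [lo, hi] Hz, unit SD
band_noise <- function(n, rate, lo, hi) {
  N <- next_fast_len(n)
  k <- 0:(N - 1)
  f <- pmin(k, N - k) * rate / N
  shape <- as.numeric(f >= lo & f <= hi)
  ph <- stats::rnorm(N) + 1i * stats::rnorm(N)
  x <- Re(stats::fft(ph * shape, inverse = TRUE))
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# smooth 0/1 state mask with ~1 s cosine ramps so components fade in/out
smooth_mask <- function(mask, rate) {
  k <- hann_window(as.integer(rate) + 1L)
  conv_same(as.numeric(mask), k / sum(k))
}

# draw a truncated normal by rejection
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Place ground-truth spindle events on a hypnogram
#'
#' Event starts follow an inhomogeneous Poisson process over NREM time with
#' intensity \code{spindle_rate_per_min / 60}, multiplied by
#' \code{pre_rem_boost} inside the final \code{pre_rem_window_s} seconds of
#' NREM episodes that end in REM. Events are non-overlapping and lie fully
#' inside their episode.
#'
#' @param hyp A \code{hypnogram}.
#' @param config A \code{synth_config}.
#' @param seed Seed; NULL continues the current RNG stream.
#' @return Data.frame with columns \code{start}, \code{end}, \code{freq_hz},
#'   \code{peak_frac} (envelope peak position), \code{amp_rel} (relative
#'   amplitude multiplier).
#' @export
generate_events <- function(hyp, config, seed = config$seed) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(config, "synth_config"))
  with_rng(seed, {
    ep <- extract_episodes(hyp)
    ep <- ep[ep$state == "NREM", , drop = FALSE]
    lam0 <- config$spindle_rate_per_min / 60
    rows <- list()
    for (i in seq_len(nrow(ep))) {
      e0 <- ep$start[i]; e1 <- ep$end[i]
      boosted <- identical(ep$successor[i], "REM") && config$pre_rem_boost != 1
      b0 <- if (boosted) max(e0, e1 - config$pre_rem_window_s) else e1
      lam_max <- lam0 * max(1, if (boosted) config$pre_rem_boost else 1)
      n_cand <- stats::rpois(1, lam_max * (e1 - e0))
      if (n_cand == 0) next
      starts <- sort(stats::runif(n_cand, e0, e1))
      lam <- ifelse(starts >= b0, lam0 * config$pre_rem_boost, lam0)
      keep <- stats::runif(n_cand) < lam / lam_max
      starts <- starts[keep]
      if (length(starts) == 0) next
      durs <- stats::runif(length(starts), config$spindle_dur_range_s[1],
                           config$spindle_dur_range_s[2])
      last_end <- -Inf
      for (j in seq_along(starts)) {
        s0 <- starts[j]; s1 <- s0 + durs[j]
        if (s0 < last_end + 0.1 || s1 > e1) next
        last_end <- s1
        rows[[length(rows) + 1L]] <- data.frame(
          start = s0, end = s1,
          freq_hz = rtruncnorm1(1, config$spindle_freq_mean_hz,
                                config$spindle_freq_sd_hz,
                                config$spindle_freq_range_hz[1],
                                config$spindle_freq_range_hz[2]),
          peak_frac = stats::runif(1, config$spindle_asym_range[1],
                                   config$spindle_asym_range[2]),
          amp_rel = 1)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(start = numeric(), end = numeric(),
                        freq_hz = numeric(), peak_frac = numeric(),
                        amp_rel = numeric())
    rownames(out) <- NULL
    out
  })
}

# asymmetric waxing-waning envelope on [0, 1] peaking at p
spindle_envelope <- function(u, p) {
  gamma <- log(0.5) / log(p)
  sin(pi * u^gamma)^2
}

#' Generate a synthetic polysomnography recording with ground truth
#'
#' Composes LFP = 1/f background + NREM slow waves + spindle bursts
#' (sinusoid at the drawn frequency under an asymmetric Hann-like envelope)
#' + wake/REM theta, and EMG = state-scaled noise. Spindle amplitude is
#' calibrated so that the peak envelope equals \code{spindle_snr} times the
#' SD of the 9-16 Hz filtered spindle-free NREM background.
#'
#' @param config A \code{synth_config}.
#' @param seed Seed (default \code{config$seed}).
#' @return List with \code{lfp}, \code{emg} (\code{eeg_signal}),
#'   \code{hypnogram}, and \code{truth} (list: \code{spindles} data.frame
#'   with start/end/freq_hz/peak_frac/phase/amp_uv, \code{sigma_sd_uv} the
#'   background sigma-band SD, \code{sw} the slow-wave component).
#' @export
generate_recording <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(seed, {
    fs <- config$rate
    hyp <- generate_hypnogram(config, seed = NULL)
    n <- as.integer(config$duration_min * 60 * fs)
    t <- (0:(n - 1)) / fs
    nrem <- state_mask(hyp, "NREM", fs, n)
    wake <- state_mask(hyp, "WAKE", fs, n)
    rem <- state_mask(hyp, "REM", fs, n)
    bg <- config$noise_scale_uv * pink_noise(n, config$noise_exponent)
    sw <- config$sw_amplitude_uv * band_noise(n, fs, 0.5, 4) *
      smooth_mask(nrem, fs)
    theta <- config$theta_amplitude_uv * band_noise(n, fs, 6, 10) *
      smooth_mask(wake | rem, fs)
    base <- bg + sw + theta
    # calibrate spindle amplitude against the sigma-band NREM background
    sig <- fir_bandpass(eeg_signal(base, fs), c(9, 16), order_at_1k = 333)
    sigma_sd <- stats::sd(sig$samples[nrem])
    amp <- config$spindle_snr * sigma_sd
    events <- generate_events(hyp, config, seed = NULL)
    if (config$sw_lock && nrow(events) > 0) {
      pk <- which(diff(sign(diff(sw))) == -2) + 1L
      pk <- pk[sw[pk] > 0]
      if (length(pk) > 0) {
        pk_t <- (pk - 1) / fs
        for (i in seq_len(nrow(events))) {
          d <- events$end[i] - events$start[i]
          ctr <- pk_t[which.min(abs(pk_t - (events$start[i] + d / 2)))]
          events$start[i] <- ctr - d / 2
          events$end[i] <- ctr + d / 2
        }
        events <- events[order(events$start), , drop = FALSE]
        if (nrow(events) > 1) {
          keep <- c(TRUE, events$start[-1] >=
                      events$end[-nrow(events)] + 0.05)
          events <- events[keep, , drop = FALSE]
        }
      }
    }
    events$phase <- stats::runif(nrow(events), 0, 2 * pi)
    events$amp_uv <- amp * events$amp_rel
    x <- base
    for (i in seq_len(nrow(events))) {
      idx <- sample_range(eeg_signal(x, fs), events$start[i], events$end[i])
      u <- (idx - idx[1]) / (length(idx) - 1L)
      env <- spindle_envelope(u, events$peak_frac[i])
      x[idx] <- x[idx] + events$amp_uv[i] * env *
        sin(2 * pi * events$freq_hz[i] * (t[idx] - t[idx[1]]) +
              events$phase[i])
    }
    emg <- config$emg_scale_uv * stats::rnorm(n) *
      (1 * wake + 0.2 * nrem + 0.05 * rem)
    list(lfp = eeg_signal(x, fs, label = "LFP"),
         emg = eeg_signal(emg, fs, label = "EMG"),
         hypnogram = hyp,
         truth = list(spindles = events, sigma_sd_uv = sigma_sd, sw = sw))
  })
}

#' Generate a spike train phase-locked to spindle cycles
#'
#' Inhomogeneous Poisson spikes: rate = \code{spike_rate_hz} outside
#' spindles; inside a spindle the rate is multiplied by
#' \code{1 + kappa * rectified cos(phase - lag)}, where phase is the phase of
#' the spindle sinusoid (0 at the LFP peak) and lag = \code{spike_lag_ms}.
#' Each spike is then replaced by a 3-spike burst (4 ms ISIs) with
#' probability \code{burst_p} when at least 50 ms of silence precedes it.
#'
#' @param recording Output of \code{\link{generate_recording}}.
#' @param config A \code{synth_config}.
#' @param seed Seed (default \code{config$seed + 1}).
#' @return List with \code{times} (sorted spike times, s) and
#'   \code{burst_starts} (times of substituted bursts).
#' @export
generate_spikes <- function(recording, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(seed, {
    fs <- config$rate
    n <- length(recording$lfp$samples)
    t <- (0:(n - 1)) / fs
    lam <- rep(config$spike_rate_hz, n)
    ev <- recording$truth$spindles
    lag <- config$spike_lag_ms / 1000
    for (i in seq_len(nrow(ev))) {
      idx <- sample_range(recording$lfp, ev$start[i], ev$end[i])
      # sinusoid sin(2*pi*f*(t-t0)+phi) peaks where its phase is pi/2
      ph <- 2 * pi * ev$freq_hz[i] * (t[idx] - lag - t[idx[1]]) +
        ev$phase[i] - pi / 2
      lam[idx] <- lam[idx] * (1 + config$spike_kappa * pmax(0, cos(ph)))
    }
    p <- lam / fs
    hit <- which(stats::runif(n) < p)
    times <- t[hit] + stats::runif(length(hit), 0, 1 / fs)
    times <- sort(times)
    # burst substitution
    burst_starts <- numeric(0)
    if (config$burst_p > 0 && length(times) > 1) {
      keep <- c(Inf, diff(times)) >= 0.05
      sub <- keep & stats::runif(length(times)) < config$burst_p
      extra <- unlist(lapply(times[sub], function(s) s + c(0.004, 0.008)))
      burst_starts <- times[sub]
      times <- sort(c(times, extra))
    }
    out <- spike_train(unique(times), unit_id = "synth",
                       source_channel = recording$lfp$label)
    attr(out, "burst_starts") <- burst_starts
    out
  })
}
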