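test_that("spike_train validates and prints", {
  tr <- spike_train(c(0.1, 0.2, 0.35), unit_id = "u7")
  expect_s3_class(tr, "spike_train")
  expect_output(print(tr), "u7: 3 spikes")
  expect_error(spike_train(c(0.2, 0.1)), "increasing")
  expect_error(spike_train(c(-1, 0.1)), "nonnegative")
})

test_that("detect_spikes recovers injected spikes and rejects noise", {
  fs <- 20000
  dur <- 5
  n <- dur * fs
  t <- (0:(n - 1)) / fs
  set.seed(31)
  noise <- rnorm(n, sd = 10)
  # pure noise: the 7.5 x median(|filtered|) threshold sits near 5 sigma
  expect_equal(length(detect_spikes(eeg_signal(noise, fs))$times), 0)
  # inject 48 large biphasic spikelets (1.5 kHz Gabor, 1 ms wide)
  true_t <- seq(0.1, 4.8, by = 0.1)
  x <- noise
  wav_t <- seq(-5e-4, 5e-4, by = 1 / fs)
  wav <- 300 * sin(2 * pi * 1500 * wav_t) * hann_window(length(wav_t))
  for (s in true_t) {
    i0 <- round(s * fs) + 1 - (length(wav) - 1) / 2
    x[i0:(i0 + length(wav) - 1)] <- x[i0:(i0 + length(wav) - 1)] + wav
  }
  tr <- detect_spikes(eeg_signal(x, fs, label = "wb"), unit_id = "cell1")
  expect_equal(tr$unit_id, "cell1")
  expect_equal(tr$source_channel, "wb")
  hits <- vapply(true_t, function(s) any(abs(tr$times - s) < 5e-4),
                 logical(1))
  expect_gte(sum(hits), 47)
  expect_lte(length(tr$times), 53)
  # contracts
  expect_warning(e0 <- detect_spikes(eeg_signal(rep(0, fs), fs)), "flat")
  expect_equal(length(e0$times), 0)
  expect_error(detect_spikes(eeg_signal(noise[1:5000], 5000)), "10 kHz")
})

test_that("burst detection follows the ISI/quiescence contract", {
  b <- detect_bursts(c(0.9, 1.0, 1.004, 1.008))
  expect_equal(nrow(b), 1)
  expect_equal(b$start_s, 1.0)
  expect_equal(b$n_spikes, 3L)
  # quiescence of only 30 ms before the run: rejected
  expect_equal(nrow(detect_bursts(c(0.97, 1.0, 1.004, 1.008))), 0)
  # a run starting the train needs no preceding silence
  b0 <- detect_bursts(c(0, 0.004, 0.008))
  expect_equal(b0$start_s, 0)
  # the 6 ms bound is exclusive
  expect_equal(nrow(detect_bursts(c(0.9, 1.0, 1.006, 1.012))), 0)
  # runs longer than the minimum are kept whole
  b4 <- detect_bursts(c(0.5, 1.0, 1.004, 1.008, 1.012))
  expect_equal(b4$n_spikes, 4L)
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
  # unit id travels through
  expect_equal(detect_bursts(spike_train(c(1, 1.004, 1.008), "u9"))$unit, "u9")
})

test_that("burst detection agrees with an independent oracle", {
  for (seed in 1:200) {
    tr <- random_spike_train(seed)
    got <- detect_bursts(tr)
    want <- brute_force_bursts(tr)
    expect_identical(got$start_s, want$start_s)
    expect_identical(got$n_spikes, want$n_spikes)
  }
})

test_that("rate_curve bins follow the window arithmetic", {
  rc <- rate_curve(list(numeric(0)), c(0, 1))
  expect_equal(rc$t[1], 0.005)
  expect_equal(rc$step_ms, 2)
  expect_equal(diff(rc$t)[1], 0.002)
  expect_true(all(rc$rate == 0))
  # one spike has unit mass: integral of the rate curve is 1 per trial
  rc1 <- rate_curve(list(0.5), c(0, 1))
  expect_equal(sum(rc1$rate) * rc1$step_ms / 1000, 1)
  # homogeneous Poisson trials recover their rate
  set.seed(41)
  trials <- replicate(200, sort(runif(rpois(1, 20), 0, 1)), simplify = FALSE)
  rcp <- rate_curve(trials, c(0, 1))
  expect_gt(mean(rcp$rate), 18)
  expect_lt(mean(rcp$rate), 22)
  expect_error(rate_curve(list(), c(0, 1)), "empty")
  expect_error(rate_curve(list(0.5), c(0, 1), window_ms = 5, overlap_ms = 5),
               "overlap")
  expect_error(rate_curve(list(0.5), c(0, 0.001)), "window")
})

test_that("central_peak picks the peak nearest the midpoint, earlier on ties", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  s <- eeg_signal(sin(2 * pi * 10 * t), fs)   # peaks at 0.025 + k/10
  # midpoint 1.2: nearest peak is 1.225 (25 ms) vs 1.125 (75 ms)
  expect_equal(central_peak(s, list(start_s = 0.95, end_s = 1.45)), 1.225)
  co <- eeg_signal(cos(2 * pi * 10 * t), fs)  # peaks at k/10
  # midpoint 0.15 is equidistant from peaks at 0.1 and 0.2 -> earlier wins
  expect_equal(central_peak(co, list(start = 0.05, end = 0.25)), 0.1)
  ramp <- eeg_signal(seq_len(1000) / 1000, fs)
  expect_error(central_peak(ramp, list(start_s = 0.2, end_s = 0.4)),
               "maximum")
})

test_that("spike-field coupling recovers locking strength and lag", {
  fs <- 1000
  dur <- 55
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  lfp <- eeg_signal(50 * sin(2 * pi * 11 * t), fs, label = "LFP")
  spindles <- data.frame(start_s = seq(5, 50, by = 5),
                         end_s = seq(5, 50, by = 5) + 1)
  # spikes: Poisson thinned by the instantaneous field, peaks at field peaks
  set.seed(55)
  lam <- 300 * (1 + sin(2 * pi * 11 * t)) / fs
  spk <- t[runif(length(t)) < lam] + 2e-4
  r0 <- spike_field_coupling(lfp, spk, spindles)
  expect_s3_class(r0, "coupling_result")
  expect_equal(r0$n_events, 10L)
  expect_gt(r0$value, 0.8)
  expect_lte(abs(r0$lag_ms), 3)
  # delaying every spike by 10 ms moves the peak lag to +10
  r10 <- spike_field_coupling(lfp, spk + 0.010, spindles)
  expect_gt(r10$value, 0.8)
  expect_lte(abs(r10$lag_ms - 10), 3)
  # invariant to LFP rescaling
  lfp5 <- eeg_signal(5 * lfp$samples, fs)
  r5 <- spike_field_coupling(lfp5, spk, spindles)
  expect_equal(r5$value, r0$value, tolerance = 1e-10)
  expect_equal(r5$lag_ms, r0$lag_ms)
  expect_error(spike_field_coupling(lfp, spk, spindles[0, ]), "spindles")
  expect_output(print(r0), "10 events")
})

test_that("SW-spindle coupling finds a constructed envelope delay", {
  fs <- 1000
  dur <- 120
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sw <- 100 * sin(2 * pi * 1 * t)
  gate <- pmax(0, sin(2 * pi * 1 * (t - 0.2)))   # envelope trails SW by 200 ms
  x <- sw + 30 * gate * sin(2 * pi * 12 * t)
  s <- eeg_signal(x, fs)
  onsets <- seq(10.2, 100.2, by = 5)             # gate openings
  spindles <- data.frame(start_s = onsets, end_s = onsets + 0.5)
  r <- sw_spindle_coupling(s, spindles)
  expect_gt(r$value, 0.6)
  expect_gt(r$lag_ms, 120)
  expect_lt(r$lag_ms, 280)
  expect_error(sw_spindle_coupling(s, spindles[0, ]), "spindles")
})

test_that("UP-state detection counts half-waves analytically", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  s <- eeg_signal(50 * sin(2 * pi * 1 * t), fs)
  up <- detect_up_states(s)
  # interior half-waves (edges are distorted by the long filter): one per
  # second, each 0.5 s long, peaking near the 50 uV amplitude
  mid <- up[up$start_s >= 5 & up$start_s < 25, , drop = FALSE]
  expect_equal(nrow(mid), 20)
  expect_true(all(abs((mid$end_s - mid$start_s) - 0.5) < 0.03))
  expect_true(all(mid$peak_uv > 40))
  # half-waves below the mean absolute amplitude are rejected
  amp <- c(rep(100, 15 * fs), rep(10, 15 * fs))
  s2 <- eeg_signal(amp * sin(2 * pi * 1 * t), fs)
  up2 <- detect_up_states(s2)
  expect_true(all(up2$end_s < 15.5))
  expect_gte(sum(up2$start_s >= 3 & up2$start_s < 13), 10)
  # 3 Hz half-waves last only 167 ms: all rejected by the duration floor
  s3 <- eeg_signal(50 * sin(2 * pi * 3 * t), fs)
  expect_equal(nrow(detect_up_states(s3)), 0)
  # inverted polarity recordings use sign = -1
  sm <- eeg_signal(-s$samples, fs)
  expect_equal(nrow(detect_up_states(sm, sign = -1)), nrow(up))
  # silence has no UP states
  expect_equal(nrow(detect_up_states(eeg_signal(rep(0, fs * 20), fs))), 0)
})

test_that("spindle-UP coincidence applies the 50% overlap rule", {
  sp <- data.frame(start_s = 1, end_s = 2)
  expect_equal(spindle_up_coincidence(sp, data.frame(start_s = 0.9,
                                                     end_s = 1.6)), 1)
  expect_equal(spindle_up_coincidence(sp, data.frame(start_s = 1.6,
                                                     end_s = 3)), 0)
  # exactly half counts
  expect_equal(spindle_up_coincidence(sp, data.frame(start_s = 1,
                                                     end_s = 1.5)), 1)
  # overlap accumulates across the UP union
  ups <- data.frame(start_s = c(1.0, 1.35), end_s = c(1.3, 1.7))
  expect_equal(spindle_up_coincidence(sp, ups), 1)
  expect_equal(spindle_up_coincidence(sp, ups[0, ]), 0)
  expect_error(spindle_up_coincidence(sp[0, ], ups), "empty")
  # both column conventions work
  expect_equal(spindle_up_coincidence(data.frame(start = 1, end = 2),
                                      data.frame(start = 0.9, end = 1.6)), 1)
})

test_that("spindle-UP coincidence matches a brute-force oracle", {
  set.seed(61)
  for (rep in 1:20) {
    sp <- data.frame(start_s = sort(runif(8, 0, 50)))
    sp$end_s <- sp$start_s + runif(8, 0.4, 1.5)
    u0 <- sort(runif(12, 0, 50))
    ups <- data.frame(start_s = u0, end_s = u0 + runif(12, 0.1, 1))
    ups <- ups[c(TRUE, ups$start_s[-1] >= ups$end_s[-12]), , drop = FALSE]
    want <- mean(vapply(seq_len(nrow(sp)), function(i) {
      ov <- 0
      for (j in seq_len(nrow(ups)))
        ov <- ov + max(0, min(sp$end_s[i], ups$end_s[j]) -
                         max(sp$start_s[i], ups$start_s[j]))
      ov >= 0.5 * (sp$end_s[i] - sp$start_s[i])
    }, logical(1)))
    expect_equal(spindle_up_coincidence(sp, ups), want)
  }
})

test_that("delta power during spindles measures the slow-wave background", {
  fs <- 500
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  A <- 80
  s <- eeg_signal(A * sin(2 * pi * 2 * t), fs)
  sp <- data.frame(start_s = c(9.8, 14.7, 20.1), end_s = c(10.6, 15.5, 20.9))
  expect_equal(delta_power_during_spindles(s, sp), A^2 / 2, tolerance = 0.1)
  # windows crossing the recording edge are dropped with a warning
  sp2 <- rbind(sp, data.frame(start_s = 29.5, end_s = 29.9))
  expect_warning(v <- delta_power_during_spindles(s, sp2), "dropped")
  expect_equal(v, A^2 / 2, tolerance = 0.1)
  expect_error(delta_power_during_spindles(s, sp[0, ]), "spindles")
  expect_error(
    suppressWarnings(
      delta_power_during_spindles(s, data.frame(start_s = 0.1, end_s = 0.5))),
    "fits")
})

test_that("rate modulation compares on/off interval rates", {
  on <- data.frame(start_s = 0, end_s = 10)
  off <- data.frame(start_s = 10, end_s = 20)
  uniform <- seq(0.5, 19.5, by = 1)
  r <- rate_modulation(uniform, on, off)
  expect_equal(r$unit_ratio, 1)
  expect_equal(r$spike_rate_on, 1)
  expect_equal(r$burst_ratio, 0)            # no bursts anywhere
  # spikes confined to the on intervals: off rate zero -> NA with warning
  expect_warning(r2 <- rate_modulation(seq(0.5, 9.5, 1), on, off), "zero")
  expect_true(is.na(r2$unit_ratio))
  # empty train: all zeros
  r0 <- rate_modulation(numeric(0), on, off)
  expect_equal(r0$unit_ratio, 0)
  expect_equal(r0$spike_rate_on, 0)
  expect_error(rate_modulation(uniform, on[0, ], off), "duration")
  # bursts concentrate in the on epoch (zero burst off-rate warns)
  bt <- c(1, 1.004, 1.008, 5, 5.004, 5.008, 12)
  expect_warning(rb <- rate_modulation(bt, on, off), "burst")
  expect_equal(rb$burst_rate_on, 0.2)
  expect_equal(rb$burst_rate_off, 0)
})
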