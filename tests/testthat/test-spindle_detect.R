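test_that("a symmetric event has symmetry exactly 0.5", {
  fs <- 1000
  n <- 5 * fs
  x <- numeric(n)
  idx <- 2001:3001                       # event [2, 3] s inclusive
  u <- seq(0, 1, length.out = length(idx))
  x[idx] <- sin(pi * u)^2 * cos(2 * pi * 11 * (u - 0.5))
  s <- eeg_signal(x, fs)
  e <- band_energy_series(s, wavelet_spec("fbsp", 2, 0.5, 1))
  sm <- smooth_energy(e, 200)
  sym <- spindle_symmetry(sm, 2, 3)
  expect_identical(as.numeric(sym), 0.5)
  expect_equal(attr(sym, "peak_t"), 2.5)
})

test_that("three injected high-SNR spindles are recovered one-for-one", {
  truth <- data.frame(start = c(10, 25, 42), end = c(11, 26.2, 42.8))
  bursts <- Map(function(s0, s1, f0) list(start = s0, end = s1, freq = f0,
                                          amp = 120),
                truth$start, truth$end, c(11, 13, 12))
  s <- make_burst_trace(60, bursts, noise_uv = 15, seed = 21)
  det <- detect_spindles(s)
  expect_s3_class(det, "spindle_detection")
  expect_equal(nrow(det$events), 3)
  # boundaries come from the low-threshold crossings, which clip the faint
  # envelope tails: each detection lies inside its burst and covers its core
  for (i in 1:3) {
    expect_gte(det$events$start_s[i], truth$start[i] - 0.15)
    expect_lte(det$events$end_s[i], truth$end[i] + 0.15)
    ov <- min(det$events$end_s[i], truth$end[i]) -
      max(det$events$start_s[i], truth$start[i])
    expect_gt(ov / (truth$end[i] - truth$start[i]), 0.5)
  }
  perf <- detection_performance(det, truth)
  expect_equal(perf$n_matched, 3L)
  # expected columns present
  expect_true(all(c("start_s", "end_s", "freq_hz", "n_cycles", "p2p_uv",
                    "symmetry") %in% names(det$events)))
  expect_equal(det$events$freq_hz, c(11, 13, 12), tolerance = 0.05)
  expect_output(print(det), "3 events")
  expect_output(summary(det), "retained events: 3")
})

test_that("count_cycles counts positive peaks of a pure tone", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  f <- eeg_signal(sin(2 * pi * 11 * t), fs)
  # positive maxima of an 11 Hz tone in [0, 1): t = (k + 1/4)/11, k = 0..10
  expect_equal(count_cycles(f, 0, 1), 11L)
  expect_equal(count_cycles(f, 0, 2), 22L)
  # fully negative trace has no positive peaks
  g <- eeg_signal(-2 + sin(2 * pi * 11 * t), fs)
  expect_equal(count_cycles(g, 0, 1), 0L)
})

test_that("dual thresholding returns maximal low-threshold runs", {
  fs <- 100
  e <- rep(1, 30 * fs)
  set.seed(9)
  # bounded jitter: can cross the lo threshold but never the hi threshold
  e <- e + runif(length(e), -0.005, 0.005)
  # bump 1 clears the hi threshold; its shoulder stays between lo and hi
  e[1001:1100] <- e[1001:1100] + 5
  e[1081:1200] <- e[1081:1200] + 0.5
  # baseline statistics from the quiet region only
  mask <- rep(TRUE, length(e)); mask[950:1250] <- FALSE
  sm <- eeg_signal(e, fs)
  ev <- threshold_events(sm, baseline_mask = mask, hi_sd = 3, lo_sd = 1)
  expect_equal(nrow(ev), 1)
  # the run extends through the low-only shoulder
  expect_lt(abs(ev$start - 10.0), 0.05)
  expect_gt(ev$end, 11.9)
  expect_true(is.numeric(attr(ev, "baseline_mean")))
  expect_true(attr(ev, "baseline_sd") > 0)
  # degenerate baseline warns and yields no events
  expect_warning(ev0 <- threshold_events(eeg_signal(rep(2, 500), fs)),
                 "SD")
  expect_equal(nrow(ev0), 0)
  expect_error(threshold_events(sm, baseline_mask = rep(FALSE, length(e))),
               "baseline")
})

test_that("band specificity separates in-band from flanking tones", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s11 <- eeg_signal(sin(2 * pi * 11 * t), fs)
  s7 <- eeg_signal(sin(2 * pi * 7 * t), fs)
  s18 <- eeg_signal(sin(2 * pi * 18 * t), fs)
  expect_true(band_specificity(s11, 0, 1))
  expect_false(band_specificity(s7, 0, 1))
  expect_false(band_specificity(s18, 0, 1))
})

test_that("central_frequency resolves off-grid tones", {
  fs <- 1000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s <- eeg_signal(sin(2 * pi * 12.3 * t) + 0.2, fs)
  expect_equal(central_frequency(s, 0, 1), 12.3, tolerance = 0.06)
})

test_that("central frequencies of matched events track the ground truth", {
  rec <- rec_small()
  det <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
  truth <- rec$truth$spindles
  diffs <- c()
  for (i in seq_len(nrow(det$events))) {
    a0 <- det$events$start_s[i]; a1 <- det$events$end_s[i]
    ov <- pmin(a1, truth$end) - pmax(a0, truth$start)
    j <- which.max(ov)
    if (ov[j] > 0.5 * (truth$end[j] - truth$start[j]))
      diffs <- c(diffs, abs(det$events$freq_hz[i] - truth$freq_hz[j]))
  }
  expect_gt(length(diffs), 3)
  expect_lt(stats::median(diffs), 0.3)
})

test_that("noise-only detections still satisfy every event filter", {
  # with no injected events the relative thresholds adapt downward, so some
  # noise excursions are emitted; they must all obey the filter contracts
  cfg <- synth_config(duration_min = 5, seed = 6, spindle_snr = 0)
  rec <- generate_recording(cfg)
  det <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
  ev <- det$events
  dur <- ev$end_s - ev$start_s
  expect_true(all(dur >= 0.4 & dur <= 2.0))
  expect_true(all(ev$n_cycles >= 5 & ev$n_cycles <= 30))
  expect_true(all(ev$freq_hz >= 9 & ev$freq_hz <= 16))
  expect_true(all(ev$symmetry >= 0 & ev$symmetry <= 1))
  # loose structural guard on the false-positive floor
  expect_lt(nrow(ev) / 5, 10)
})

test_that("detection is deterministic and amplitude-scale invariant", {
  rec <- rec_small()
  d1 <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
  d2 <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
  expect_identical(d1$events, d2$events)
  s3 <- eeg_signal(3 * rec$lfp$samples, rec$lfp$rate, label = rec$lfp$label)
  d3 <- detect_spindles(s3, hyp = rec$hypnogram)
  expect_equal(d3$events$start_s, d1$events$start_s)
  expect_equal(d3$events$end_s, d1$events$end_s)
  expect_equal(d3$events$p2p_uv, 3 * d1$events$p2p_uv, tolerance = 1e-8)
})

test_that("sensitivity increases with event SNR", {
  sens <- vapply(c(2, 8), function(snr) {
    cfg <- synth_config(duration_min = 5, seed = 11, spindle_snr = snr)
    rec <- generate_recording(cfg)
    det <- detect_spindles(rec$lfp, hyp = rec$hypnogram)
    detection_performance(det, rec$truth$spindles)$sensitivity
  }, numeric(1))
  expect_gt(sens[2], sens[1])
})

test_that("detection_performance matches greedily one-to-one", {
  det <- data.frame(start_s = c(1.0, 5.0, 9.0), end_s = c(2.0, 6.0, 9.5))
  truth <- data.frame(start = c(1.1, 20), end = c(2.1, 21))
  perf <- detection_performance(det, truth)
  expect_equal(perf$n_matched, 1L)
  expect_equal(perf$sensitivity, 0.5)
  expect_equal(perf$fdr, 2 / 3)
  # each truth interval can absorb only one detection
  det2 <- data.frame(start_s = c(1.0, 1.2), end_s = c(2.0, 2.2))
  perf2 <- detection_performance(det2, truth)
  expect_equal(perf2$n_matched, 1L)
  # empty inputs
  p0 <- detection_performance(det[0, ], truth)
  expect_equal(p0$sensitivity, 0)
  expect_true(is.na(p0$fdr))
})

test_that("spindle_config validates its thresholds", {
  expect_error(spindle_config(hi_sd = 1, lo_sd = 2), "hi_sd")
  expect_error(spindle_config(min_dur_s = 3, max_dur_s = 2), "dur")
  expect_error(spindle_config(min_cycles = 30, max_cycles = 5), "cycles")
})
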