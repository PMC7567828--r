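test_that("hypnograms are deterministic and follow the state grammar", {
  cfg <- synth_config(duration_min = 120, seed = 2)
  h1 <- generate_hypnogram(cfg)
  h2 <- generate_hypnogram(cfg)
  expect_identical(h1$labels, h2$labels)
  expect_equal(hypnogram_duration(h1), 120 * 60)
  expect_true(all(h1$labels %in% c("WAKE", "NREM", "REM")))
  ep <- extract_episodes(h1)
  # wake leads only to NREM; REM is entered only from NREM
  expect_true(all(ep$successor[ep$state == "WAKE"] == "NREM", na.rm = TRUE))
  expect_true(all(ep$state[which(ep$successor == "REM")] == "NREM"))
  expect_true(all(ep$successor[ep$state == "REM"] == "WAKE", na.rm = TRUE))
})

test_that("NREM bout durations match the configured mean", {
  cfg <- synth_config(duration_min = 600, seed = 3)
  ep <- extract_episodes(generate_hypnogram(cfg))
  ep <- ep[-nrow(ep), , drop = FALSE]        # last bout is truncated
  dur <- with(ep[ep$state == "NREM", ], end - start)
  expect_gt(length(dur), 100)
  expect_lt(abs(mean(dur) - cfg$nrem_mean_s) / cfg$nrem_mean_s, 0.2)
  expect_true(all(dur >= cfg$nrem_min_s))
})

test_that("ground-truth events respect the generator contracts", {
  cfg <- synth_config(duration_min = 200, seed = 4)
  hyp <- generate_hypnogram(cfg)
  ev <- generate_events(hyp, cfg)
  expect_gt(nrow(ev), 50)
  expect_identical(ev, generate_events(hyp, cfg))
  dur <- ev$end - ev$start
  expect_true(all(dur >= cfg$spindle_dur_range_s[1] &
                    dur <= cfg$spindle_dur_range_s[2]))
  expect_true(all(ev$freq_hz >= cfg$spindle_freq_range_hz[1] &
                    ev$freq_hz <= cfg$spindle_freq_range_hz[2]))
  # every event lies inside an NREM episode; successive events keep a gap
  for (i in seq_len(nrow(ev))) {
    expect_equal(state_at(hyp, ev$start[i]), "NREM")
    expect_equal(state_at(hyp, ev$end[i] - 1e-9), "NREM")
  }
  expect_true(all(diff(ev$start) > 0))
  expect_true(all(ev$start[-1] - ev$end[-nrow(ev)] >= 0.1 - 1e-9))
  # an all-wake hypnogram yields no events
  ev0 <- generate_events(hypnogram(rep("WAKE", 600)), cfg)
  expect_equal(nrow(ev0), 0)
})

pre_rem_ratio <- function(cfg) {
  hyp <- generate_hypnogram(cfg)
  ev <- generate_events(hyp, cfg)
  ep <- extract_episodes(hyp)
  ep <- ep[ep$state == "NREM" & !is.na(ep$successor) &
             ep$successor == "REM" & (ep$end - ep$start) >= 50, , drop = FALSE]
  n_win <- 0; min_win <- 0; n_all <- 0; min_all <- 0
  for (i in seq_len(nrow(ep))) {
    w0 <- ep$end[i] - cfg$pre_rem_window_s
    n_win <- n_win + sum(ev$start >= w0 & ev$start < ep$end[i])
    min_win <- min_win + cfg$pre_rem_window_s / 60
    n_all <- n_all + sum(ev$start >= ep$start[i] & ev$start < ep$end[i])
    min_all <- min_all + (ep$end[i] - ep$start[i]) / 60
  }
  (n_win / min_win) / (n_all / min_all)
}

test_that("pre-REM enrichment is present exactly when the boost is on", {
  r_flat <- pre_rem_ratio(synth_config(duration_min = 1500, seed = 8,
                                       pre_rem_boost = 1))
  expect_gt(r_flat, 0.8)
  expect_lt(r_flat, 1.25)
  r_boost <- pre_rem_ratio(synth_config(duration_min = 1500, seed = 8))
  expect_gt(r_boost, 1.5 * r_flat)
})

test_that("recordings are deterministic with calibrated spindle amplitude", {
  cfg <- synth_config(duration_min = 3, seed = 12)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$lfp$samples, r2$lfp$samples)
  expect_identical(r1$truth$spindles, r2$truth$spindles)
  expect_equal(r1$lfp$rate, cfg$rate)
  expect_equal(length(r1$lfp$samples), 3 * 60 * cfg$rate)
  expect_true(all(c("start", "end", "freq_hz", "phase", "amp_uv") %in%
                    names(r1$truth$spindles)))
  # amplitudes are SNR x sigma-band background SD
  expect_equal(unique(r1$truth$spindles$amp_uv),
               cfg$spindle_snr * r1$truth$sigma_sd_uv)
})

test_that("doubling the slow-wave amplitude multiplies NREM delta power", {
  p <- vapply(c(100, 200), function(a) {
    cfg <- synth_config(duration_min = 5, seed = 9, sw_amplitude_uv = a)
    rec <- generate_recording(cfg)
    nrem <- state_mask(rec$hypnogram, "NREM", rec$lfp$rate,
                       length(rec$lfp$samples))
    bandpower(rec$lfp$samples[nrem], c(0.5, 4), rate = rec$lfp$rate)
  }, numeric(1))
  expect_gt(p[2] / p[1], 2.5)
  expect_lt(p[2] / p[1], 4.5)
})

test_that("unmodulated spike trains are Poisson", {
  cfg <- synth_config(duration_min = 10, seed = 5, spike_kappa = 0,
                      burst_p = 0)
  rec <- generate_recording(cfg)
  tr <- generate_spikes(rec, cfg)
  expect_s3_class(tr, "spike_train")
  expect_identical(tr$times, generate_spikes(rec, cfg)$times)
  isi <- diff(tr$times)
  n <- length(isi)
  expect_gt(n, 3000)
  # KS distance to the fitted exponential below the 5% critical value
  d <- max(abs(stats::ecdf(isi)(sort(isi)) -
                 stats::pexp(sort(isi), rate = 1 / mean(isi))))
  expect_lt(d, 1.36 / sqrt(n))
})

test_that("burst substitution inserts 4 ms doublets after quiescence", {
  cfg <- synth_config(duration_min = 5, seed = 7, burst_p = 0.5)
  rec <- generate_recording(cfg)
  tr <- generate_spikes(rec, cfg)
  bs <- attr(tr, "burst_starts")
  expect_gt(length(bs), 10)
  for (s in bs[1:10]) {
    expect_true(any(abs(tr$times - (s + 0.004)) < 1e-9))
    expect_true(any(abs(tr$times - (s + 0.008)) < 1e-9))
  }
})

test_that("phase locking raises the in-spindle spike rate", {
  cfg <- synth_config(duration_min = 15, seed = 10, spike_kappa = 1,
                      burst_p = 0)
  rec <- generate_recording(cfg)
  tr <- generate_spikes(rec, cfg)
  ev <- rec$truth$spindles
  t_in <- sum(ev$end - ev$start)
  n_in <- sum(vapply(seq_len(nrow(ev)), function(i)
    sum(tr$times >= ev$start[i] & tr$times < ev$end[i]), numeric(1)))
  total <- signal_duration(rec$lfp)
  rate_out <- (length(tr$times) - n_in) / (total - t_in)
  # mean factor over a cycle is 1 + kappa/pi ~ 1.32 at kappa = 1
  expect_gt(n_in / t_in, 1.1 * rate_out)
})
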