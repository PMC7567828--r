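# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small full recording shared by several suites
rec_small <- function() fixture("rec_small", {
  generate_recording(synth_config(duration_min = 5, seed = 5))
})

# pink-like background of a given sigma-band SD with injected tone bursts
make_burst_trace <- function(dur_s, bursts, rate = 1000, noise_uv = 20,
                             seed = 1) {
  set.seed(seed)
  n <- as.integer(dur_s * rate)
  f <- seq(0, rate - rate / n, length.out = n)
  f[f > rate / 2] <- rate - f[f > rate / 2]
  shape <- 1 / pmax(f, 0.1)
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE))
  x <- x / stats::sd(x) * noise_uv
  for (b in bursts) {
    idx <- which((seq_len(n) - 1) / rate >= b$start &
                   (seq_len(n) - 1) / rate < b$end)
    u <- seq(0, 1, length.out = length(idx))
    x[idx] <- x[idx] + b$amp * sin(2 * pi * b$freq * (u * (b$end - b$start))) *
      (0.5 - 0.5 * cos(2 * pi * u))
  }
  eeg_signal(x, rate)
}

# independent brute-force burst scan used as the oracle
brute_force_bursts <- function(t, max_isi_ms = 6, min_spikes = 3,
                               quiescence_ms = 50) {
  res <- list()
  n <- length(t)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (t[j + 1L] - t[j]) * 1000 < max_isi_ms) j <- j + 1L
    len <- j - i + 1L
    ok_quiet <- i == 1L || (t[i] - t[i - 1L]) * 1000 >= quiescence_ms
    if (len >= min_spikes && ok_quiet)
      res[[length(res) + 1L]] <- data.frame(start_s = t[i], n_spikes = len,
                                            unit = "u1",
                                            stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(res) == 0L)
    return(data.frame(start_s = numeric(0), n_spikes = integer(0),
                      unit = character(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

random_spike_train <- function(seed) {
  set.seed(seed)
  n <- stats::rpois(1, 30)
  if (n == 0) return(numeric(0))
  # mixture of sparse background and dense clusters to exercise the burst rules
  t <- stats::runif(n, 0, 10)
  k <- stats::rpois(1, 3)
  if (k > 0) {
    centers <- stats::runif(k, 0, 10)
    for (cc in centers) {
      m <- sample(2:5, 1)
      t <- c(t, cc + cumsum(stats::runif(m, 0.001, 0.008)))
    }
  }
  sort(unique(t))
}
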