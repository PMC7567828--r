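#' Construct a single-channel signal
#'
#' A signal is one channel of uniformly sampled voltage in microvolts (uV),
#' the substrate of all filtering and event detection in the package.
#'
#' @param samples Numeric vector of voltages (uV). Must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param label Channel name.
#' @param t0 Start time of the first sample in seconds from recording start.
#' @return An object of class \code{eeg_signal}: a list with elements
#'   \code{samples}, \code{rate}, \code{label} and \code{t0}.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 12 * seq(0, 1, by = 1e-3)), rate = 1000)
#' s
#' @export
eeg_signal <- function(samples, rate, label = "ch1", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(
    list(samples = samples, rate = as.numeric(rate),
         label = as.character(label), t0 = as.numeric(t0)),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> channel '%s': %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$label, length(x$samples), x$rate,
              length(x$samples) / x$rate, x$t0))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param x An \code{eeg_signal}.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "eeg_signal"))
  length(x$samples) / x$rate
}

#' Sample times of a signal
#' @param x An \code{eeg_signal}.
#' @return Numeric vector of sample times (s).
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "eeg_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$rate
}

#' Vigilance state labels used throughout the package
#' @export
VIGILANCE_STATES <- c("WAKE", "NREM", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of vigilance-state labels (WAKE/NREM/REM) at a
#' fixed epoch resolution; epoch k covers the half-open interval
#' \[k*epoch_s, (k+1)*epoch_s) seconds from recording start.
#'
#' @param labels Character vector over \code{c("WAKE", "NREM", "REM")}.
#' @param epoch_s Epoch length in seconds (default 1).
#' @return An object of class \code{hypnogram}.
#' @examples
#' hypnogram(c("WAKE", "NREM", "NREM", "REM"))
#' @export
hypnogram <- function(labels, epoch_s = 1) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad) > 0L)
    stop("unknown vigilance labels: ", paste(bad, collapse = ", "))
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch_s must be > 0")
  structure(list(labels = labels, epoch_s = as.numeric(epoch_s)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs of %g s (%.1f min total)\n",
              length(x$labels), x$epoch_s,
              length(x$labels) * x$epoch_s / 60))
  for (s in VIGILANCE_STATES)
    cat(sprintf("  %s: %.1f min\n", s, tab[[s]] * x$epoch_s / 60))
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' Total duration of a hypnogram in seconds
#' @param x A \code{hypnogram}.
#' @return Duration in seconds.
#' @export
hypnogram_duration <- function(x) {
  stopifnot(inherits(x, "hypnogram"))
  length(x$labels) * x$epoch_s
}

#' State label at given times
#' @param x A \code{hypnogram}.
#' @param t Times in seconds.
#' @return Character vector of labels; NA outside the hypnogram span.
#' @export
state_at <- function(x, t) {
  stopifnot(inherits(x, "hypnogram"))
  k <- floor(t / x$epoch_s) + 1
  out <- rep(NA_character_, length(t))
  ok <- k >= 1 & k <= length(x$labels)
  out[ok] <- x$labels[k[ok]]
  out
}

# Interval helpers ------------------------------------------------------------
# Intervals are plain data.frames with numeric columns start/end (seconds),
# half-open [start, end).

#' Construct an interval table
#' @param start,end Numeric vectors of interval bounds in seconds; each
#'   interval is half-open \[start, end) and must satisfy end > start.
#' @return A data.frame with columns \code{start} and \code{end}.
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (any(end <= start)) stop("intervals must satisfy end > start")
  data.frame(start = start, end = end)
}

# total length of the intersection of [a0,a1) with the union of rows of iv
interval_overlap <- function(a0, a1, iv) {
  if (nrow(iv) == 0L) return(0)
  lo <- pmax(a0, iv$start)
  hi <- pmin(a1, iv$end)
  sum(pmax(0, hi - lo))
}

#' Extract maximal same-state episodes from a hypnogram
#'
#' An episode is a maximal run of identical vigilance labels together with the
#' label of the following run (its successor); the final episode has successor
#' \code{NA}. Episode intervals partition the hypnogram duration exactly.
#'
#' @param hyp A \code{hypnogram}.
#' @param min_dur_s Minimum episode duration in seconds; shorter episodes are
#'   dropped from the returned table (their time is not re-assigned). Default 0
#'   keeps strict maximal runs.
#' @return A data.frame with columns \code{start}, \code{end} (s),
#'   \code{state}, \code{successor} (NA for the final episode).
#' @examples
#' h <- hypnogram(c("NREM", "NREM", "REM", "REM", "WAKE"))
#' extract_episodes(h)
#' @export
extract_episodes <- function(hyp, min_dur_s = 0) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths) * hyp$epoch_s
  starts <- c(0, ends[-length(ends)])
  succ <- c(r$values[-1], NA_character_)
  ep <- data.frame(start = starts, end = ends, state = r$values,
                   successor = succ, stringsAsFactors = FALSE)
  ep[ep$end - ep$start >= min_dur_s, , drop = FALSE]
}

#' Per-sample mask of a vigilance state
#'
#' @param hyp A \code{hypnogram}.
#' @param state One of \code{"WAKE"}, \code{"NREM"}, \code{"REM"}.
#' @param rate Sampling rate of the signal the mask applies to (Hz);
#'   \code{rate * epoch_s} must be integral.
#' @param n_samples Length of the returned mask. If the hypnogram is shorter
#'   than the signal the tail is \code{FALSE} and a warning is raised.
#' @return Logical vector of length \code{n_samples}.
#' @export
state_mask <- function(hyp, state, rate, n_samples) {
  stopifnot(inherits(hyp, "hypnogram"))
  state <- match.arg(state, VIGILANCE_STATES)
  spe <- rate * hyp$epoch_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("rate * epoch_s must be an integer number of samples")
  spe <- as.integer(round(spe))
  full <- rep(hyp$labels == state, each = spe)
  if (length(full) < n_samples) {
    warning("hypnogram shorter than signal; tail of mask set to FALSE")
    full <- c(full, rep(FALSE, n_samples - length(full)))
  } else if (length(full) > n_samples) {
    full <- full[seq_len(n_samples)]
  }
  full
}
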