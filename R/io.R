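# Readers/writers for signals (EDF, raw float32 + JSON sidecar), hypnograms,
# event tables and spike-time lists, plus the anti-alias decimation applied to
# raw wide-band acquisitions.

# --- EDF ---------------------------------------------------------------------
# Minimal continuous EDF: 256-byte fixed header, 256 bytes of per-signal header
# fields (field-major layout), then data records of little-endian int16.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' Writes a continuous multi-channel EDF file. All channels must have rates
#' that are integral per data record. Samples are scaled to the int16 digital
#' range using per-channel physical min/max.
#'
#' @param signals A list of \code{eeg_signal} objects (equal durations).
#' @param path Output file path.
#' @param record_s Data-record duration in seconds (default 1).
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(signals, path, record_s = 1) {
  if (inherits(signals, "eeg_signal")) signals <- list(signals)
  ns <- length(signals)
  stopifnot(ns >= 1)
  spr <- vapply(signals, function(s) s$rate * record_s, numeric(1))
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("each channel rate * record_s must be integral")
  spr <- as.integer(round(spr))
  n_rec <- ceiling(length(signals[[1]]$samples) / spr[1])
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(format(record_s), 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  pmin_ <- vapply(signals, function(s) min(s$samples, -1), numeric(1))
  pmax_ <- vapply(signals, function(s) max(s$samples, 1), numeric(1))
  field <- function(vals, width) writeChar(paste0(edf_pad(vals, width), collapse = ""),
                                           con, eos = NULL)
  field(vapply(signals, `[[`, "", "label"), 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(spr, 8)
  field(rep("", ns), 32)                       # reserved
  gain <- (pmax_ - pmin_) / (32767 - (-32768))
  total <- n_rec * spr
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]$samples
    if (length(x) < total[i]) x <- c(x, rep(0, total[i] - length(x)))
    d <- round((x - pmin_[i]) / gain[i] + (-32768))
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read signals from an EDF file
#'
#' @param path Path to a continuous EDF file.
#' @return A list of \code{eeg_signal} objects, one per channel, in uV
#'   (mV channels are converted).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fields(16); fields(80)
  dims <- fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8)); fields(32)
  seek(con, hdr_bytes)
  expected <- sum(spr) * n_rec
  raw_all <- readBin(con, integer(), n = expected, size = 2,
                     signed = TRUE, endian = "little")
  if (length(raw_all) != expected)
    stop("EDF payload truncated: expected ", expected, " samples, got ",
         length(raw_all))
  out <- vector("list", ns)
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  rec_len <- sum(spr)
  offs <- c(0, cumsum(spr))
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1) * rec_len, `+`))
    x <- (raw_all[idx] - dmin_[i]) * gain[i] + pmin_[i]
    scale <- if (grepl("^mV$", dims[i], ignore.case = TRUE)) 1000 else 1
    out[[i]] <- eeg_signal(x * scale, rate = spr[i] / record_s,
                           label = labels[i])
  }
  names(out) <- labels
  out
}

# --- raw binary + JSON sidecar ----------------------------------------------

#' Write signals as little-endian float32 with a JSON sidecar
#'
#' Channels are interleaved sample-major per channel block (channel 1's full
#' trace, then channel 2's, ...). The sidecar (\code{<path>.json}) records
#' rate, labels, units and per-channel lengths.
#'
#' @param signals List of \code{eeg_signal}.
#' @param path Output binary path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
write_raw_binary <- function(signals, path) {
  if (inherits(signals, "eeg_signal")) signals <- list(signals)
  con <- file(path, "wb")
  on.exit(close(con))
  for (s in signals) writeBin(s$samples, con, size = 4, endian = "little")
  meta <- list(
    format = "float32-le",
    units = "uV",
    rate = vapply(signals, `[[`, numeric(1), "rate"),
    labels = vapply(signals, `[[`, character(1), "label"),
    n_samples = vapply(signals, function(s) length(s$samples), numeric(1))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read signals written by \code{write_raw_binary}
#' @param path Path to the binary file (sidecar expected at
#'   \code{<path>.json}).
#' @return List of \code{eeg_signal}.
#' @export
read_raw_binary <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_total <- sum(meta$n_samples)
  x <- readBin(path, numeric(), n = n_total + 1, size = 4, endian = "little")
  if (length(x) != n_total)
    stop("payload length ", length(x), " does not match sidecar total ",
         n_total)
  offs <- c(0, cumsum(meta$n_samples))
  out <- lapply(seq_along(meta$labels), function(i) {
    eeg_signal(x[(offs[i] + 1):offs[i + 1]], rate = meta$rate[i],
               label = meta$labels[i])
  })
  names(out) <- meta$labels
  out
}

#' Read signals from a supported container
#' @param path File path.
#' @param format \code{"edf"} or \code{"raw"} (float32 + JSON sidecar).
#' @return List of \code{eeg_signal}.
#' @export
read_signals <- function(path, format = c("edf", "raw")) {
  format <- match.arg(format)
  switch(format, edf = read_edf(path), raw = read_raw_binary(path))
}

# --- hypnogram CSV -----------------------------------------------------------

default_label_map <- c(
  W = "WAKE", WAKE = "WAKE", wake = "WAKE", w = "WAKE",
  N = "NREM", NREM = "NREM", nrem = "NREM", n = "NREM", S = "NREM",
  R = "REM", REM = "REM", rem = "REM", r = "REM"
)

#' Read a hypnogram from CSV
#'
#' Accepts either one label per row (header \code{state}) or a run-length
#' dialect with columns \code{state,count}. Labels are mapped onto
#' WAKE/NREM/REM via \code{label_map}; unmapped labels are an error.
#'
#' @param path CSV path.
#' @param epoch_s Epoch length in seconds (default 1).
#' @param label_map Named character vector mapping file labels to
#'   WAKE/NREM/REM.
#' @return A \code{hypnogram}.
#' @export
read_hypnogram <- function(path, epoch_s = 1, label_map = default_label_map) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, header = FALSE)
  if (nrow(d) == 0L) stop("empty hypnogram file: ", path)
  # tolerate an optional header row
  if (tolower(as.character(d[1, 1])) %in% c("state", "stage", "label"))
    d <- d[-1, , drop = FALSE]
  if (nrow(d) == 0L) stop("hypnogram file holds only a header: ", path)
  raw <- as.character(d[[1]])
  counts <- if (ncol(d) >= 2L) as.integer(d[[2]]) else rep(1L, nrow(d))
  mapped <- unname(label_map[raw])
  if (anyNA(mapped))
    stop("unmappable vigilance labels: ",
         paste(unique(raw[is.na(mapped)]), collapse = ", "))
  hypnogram(rep(mapped, counts), epoch_s = epoch_s)
}

#' Write a hypnogram to CSV (one label per row, header \code{state})
#' @param hyp A \code{hypnogram}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(data.frame(state = hyp$labels), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# --- event tables ------------------------------------------------------------

event_columns <- c("start_s", "end_s", "channel", "state", "freq_hz",
                   "n_cycles", "p2p_uv", "symmetry")

#' Write a spindle event table to CSV
#'
#' @param events Data.frame with (at least) columns \code{start_s,end_s};
#'   the remaining canonical columns (\code{channel,state,freq_hz,n_cycles,
#'   p2p_uv,symmetry}) are filled with NA when absent. Must be sorted by
#'   \code{start_s}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as.data.frame(events)
  if (nrow(events) > 0L && is.unsorted(events$start_s))
    stop("events must be sorted by start_s")
  for (col in event_columns)
    if (is.null(events[[col]])) events[[col]] <- NA
  out <- events[, event_columns, drop = FALSE]
  num <- setdiff(event_columns, c("channel", "state", "n_cycles"))
  for (col in num) out[[col]] <- formatC(out[[col]], digits = 6, format = "f")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spindle event table written by \code{write_events}
#' @param path CSV path.
#' @return Data.frame with the canonical event columns.
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("start_s", "end_s"), names(d))
  if (length(missing)) stop("event table lacks columns: ",
                            paste(missing, collapse = ", "))
  d
}

#' Read spike times from CSV (columns \code{t_s,unit})
#' @param path CSV path.
#' @return Data.frame with columns \code{t_s} (numeric, sorted within unit)
#'   and \code{unit}.
#' @export
read_spike_times <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$t_s)) stop("spike table lacks column t_s")
  if (is.null(d$unit)) d$unit <- "u1"
  d[order(d$unit, d$t_s), , drop = FALSE]
}

# --- acquisition chain -------------------------------------------------------

#' Anti-alias decimation to a target rate
#'
#' Applies a zero-phase Chebyshev Type-I order-8 low-pass (passband edge at
#' 0.4 x target rate, i.e. 400 Hz for the default 1000 Hz target; 0.05 dB
#' passband ripple) and keeps every (rate/target)-th sample, the standard
#' chain for reducing wide-band acquisitions to LFP/EEG rates.
#'
#' @param signal An \code{eeg_signal} with \code{rate} an integer multiple of
#'   \code{target_rate}.
#' @param target_rate Target sampling rate in Hz (default 1000).
#' @return Decimated \code{eeg_signal} at \code{target_rate}. When the factor
#'   is 1 the filter is still applied.
#' @export
decimate_to_target <- function(signal, target_rate = 1000) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (signal$rate < target_rate) stop("signal rate below target rate")
  factor <- signal$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("rate must be an integer multiple of target_rate")
  factor <- as.integer(round(factor))
  edge <- 0.4 * target_rate
  flt <- signal::cheby1(8, 0.05, edge / (signal$rate / 2), "low")
  y <- signal::filtfilt(flt, signal$samples)
  if (factor > 1L) y <- y[seq(1L, length(y), by = factor)]
  eeg_signal(y, rate = target_rate, label = signal$label, t0 = signal$t0)
}
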