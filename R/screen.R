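# Wavelet-family screening: rank candidate mother wavelets by normalized
# spindle power (ratio of mean wavelet energy inside annotated spindles to
# the mean outside) with a grid search over each family's free parameters.

#' Normalized spindle power of a wavelet on annotated data
#'
#' Ratio between the mean 9-16 Hz wavelet energy over samples inside the
#' annotated spindle intervals and the mean over samples outside; the
#' screening criterion for wavelet choice. Invariant to global amplitude
#' rescaling of the signal.
#'
#' @param signal An \code{eeg_signal}.
#' @param spindle_intervals Data.frame with \code{start}, \code{end} (s).
#' @param wavelet A \code{wavelet_spec}.
#' @param band Screening band (Hz), fixed to the detection band by default.
#' @param step_hz Frequency-grid spacing (Hz).
#' @param hyp Optional \code{hypnogram}: both means are then restricted to
#'   NREM samples, matching the stage-restricted recordings the screening is
#'   defined on (spindle-free wake/REM theta would otherwise contaminate the
#'   denominator).
#' @return Dimensionless ratio >= 0.
#' @export
normalized_spindle_power <- function(signal, spindle_intervals, wavelet,
                                     band = c(9, 16), step_hz = 0.5,
                                     hyp = NULL) {
  stopifnot(inherits(signal, "eeg_signal"))
  if (is.null(spindle_intervals) || nrow(spindle_intervals) == 0L)
    stop("no annotated spindle intervals")
  e <- band_energy_series(signal, wavelet, band, step_hz)
  inside <- rep(FALSE, length(e$samples))
  for (i in seq_len(nrow(spindle_intervals)))
    inside[sample_range(e, spindle_intervals$start[i],
                        spindle_intervals$end[i])] <- TRUE
  scope <- if (!is.null(hyp))
    state_mask(hyp, "NREM", e$rate, length(e$samples))
  else rep(TRUE, length(e$samples))
  if (!any(scope & !inside)) stop("no spindle-free samples in scope")
  if (!any(scope & inside)) stop("no annotated samples in scope")
  mean(e$samples[inside & scope]) / mean(e$samples[!inside & scope])
}

#' Default parameter grid for a wavelet family
#'
#' Families with free parameters (fbsp, cmor, shan) get the documented
#' default grid (order 1-3, bandwidth 0.5-2, center frequency 0.5-1.5);
#' fixed families get a single point.
#'
#' @param family Family name.
#' @return Data.frame with columns \code{order_m}, \code{bandwidth_fb},
#'   \code{center_fc}.
#' @export
default_wavelet_grid <- function(family) {
  fams <- wavelet_families()
  if (!family %in% names(fams)) stop("unsupported wavelet family: ", family)
  pars <- fams[[family]]$params
  grid <- expand.grid(
    order_m = if ("order_m" %in% pars) c(1L, 2L, 3L) else 2L,
    bandwidth_fb = if ("bandwidth_fb" %in% pars) c(0.5, 1, 1.5, 2) else 1,
    center_fc = if ("center_fc" %in% pars) c(0.5, 1, 1.5) else 1,
    KEEP.OUT.ATTRS = FALSE
  )
  unique(grid)
}

#' Grid search over a wavelet family's free parameters
#'
#' Evaluates \code{\link{normalized_spindle_power}} on every grid point and
#' returns the maximizer (first occurrence on ties, so the search is
#' deterministic).
#'
#' @param signal An \code{eeg_signal}.
#' @param spindle_intervals Annotated intervals (\code{start}, \code{end}).
#' @param family Family name.
#' @param grid Data.frame of parameter combinations (default
#'   \code{\link{default_wavelet_grid}}).
#' @param band,step_hz Screening band and grid spacing.
#' @return List of class \code{screen_result}: \code{wavelet} (the best
#'   \code{wavelet_spec}), \code{normalized_power}, \code{family},
#'   \code{grid} (the evaluated grid with a \code{normalized_power} column).
#' @export
grid_search_wavelet <- function(signal, spindle_intervals, family,
                                grid = default_wavelet_grid(family),
                                band = c(9, 16), step_hz = 0.5,
                                hyp = NULL) {
  if (is.null(grid) || nrow(grid) == 0L) stop("empty parameter grid")
  ratios <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    wv <- wavelet_spec(family, order_m = grid$order_m[i],
                       bandwidth_fb = grid$bandwidth_fb[i],
                       center_fc = grid$center_fc[i])
    ratios[i] <- normalized_spindle_power(signal, spindle_intervals, wv,
                                          band, step_hz, hyp)
  }
  best <- which.max(ratios)
  grid$normalized_power <- ratios
  structure(list(
    wavelet = wavelet_spec(family, order_m = grid$order_m[best],
                           bandwidth_fb = grid$bandwidth_fb[best],
                           center_fc = grid$center_fc[best]),
    normalized_power = ratios[best], family = family, grid = grid),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: normalized spindle power %.3f (m=%d, fb=%g, fc=%g)\n",
              x$family, x$normalized_power, x$wavelet$order_m,
              x$wavelet$bandwidth_fb, x$wavelet$center_fc))
  invisible(x)
}

#' Rank wavelet families by normalized spindle power
#'
#' Grid-searches each family and sorts the results by descending normalized
#' spindle power (the screening that motivates the complex frequency
#' B-spline as the detection wavelet).
#'
#' @param signal An \code{eeg_signal}.
#' @param spindle_intervals Annotated intervals.
#' @param families Character vector of family names (>= 2), default all 15.
#' @param band,step_hz Screening band and grid spacing.
#' @return Data.frame sorted by descending \code{normalized_power} with the
#'   chosen parameters per family; attribute \code{results} holds the full
#'   \code{screen_result} list.
#' @export
rank_families <- function(signal, spindle_intervals,
                          families = wavelet_family_names(),
                          band = c(9, 16), step_hz = 0.5, hyp = NULL) {
  if (length(families) < 2L) stop("need at least two families to rank")
  res <- lapply(families, function(f)
    grid_search_wavelet(signal, spindle_intervals, f, band = band,
                        step_hz = step_hz, hyp = hyp))
  tab <- data.frame(
    family = families,
    normalized_power = vapply(res, `[[`, numeric(1), "normalized_power"),
    order_m = vapply(res, function(r) r$wavelet$order_m, integer(1)),
    bandwidth_fb = vapply(res, function(r) r$wavelet$bandwidth_fb,
                          numeric(1)),
    center_fc = vapply(res, function(r) r$wavelet$center_fc, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$normalized_power)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- res[ord]
  tab
}

#' Read annotated spindle intervals from CSV (\code{start_s,end_s} per row)
#' @param path CSV path.
#' @return Data.frame with \code{start}, \code{end}.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(d$start_s) || is.null(d$end_s))
    stop("annotation CSV needs columns start_s,end_s")
  intervals(d$start_s, d$end_s)
}

#' Read DREAMS-style annotations (onset + duration, whitespace separated)
#' @param path Text file with two numeric columns: onset (s) and
#'   duration (s); lines starting with non-numeric text are skipped.
#' @return Data.frame with \code{start}, \code{end}.
#' @export
read_dreams_annotations <- function(path) {
  ln <- readLines(path)
  ln <- ln[grepl("^\\s*[0-9]", ln)]
  if (length(ln) == 0L) stop("no numeric annotation lines in ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(ln), "\\s+"), function(p)
    as.numeric(p[1:2])))
  intervals(m[, 1], m[, 1] + m[, 2])
}
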