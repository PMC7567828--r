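# Spindle-rate statistics across vigilance states: per-state rates, episode
# rates split by successor state (N2R vs N2W), pre-transition window
# profiles, and slow moving-window rate dynamics.

events_in_window <- function(events, t0, t1) {
  if (is.null(events) || nrow(events) == 0L) return(0L)
  sum(events$start_s >= t0 & events$start_s < t1)
}

#' Event rate per vigilance state
#'
#' Counts state-labelled events and divides by the total dwell time of each
#' state. States with zero dwell time get an \code{NA} rate (undefined, not
#' zero).
#'
#' @param events Data.frame with \code{start_s} and \code{state} columns
#'   (e.g. \code{spindle_detection$events}).
#' @param hyp A \code{hypnogram}.
#' @return Data.frame with one row per vigilance state: \code{state},
#'   \code{n_events}, \code{minutes}, \code{rate} (events per minute;
#'   \code{NA} when the state never occurs).
#' @examples
#' hyp <- hypnogram(rep(c("WAKE", "NREM"), each = 300))
#' ev <- data.frame(start_s = c(310, 400, 550), state = "NREM")
#' rate_by_state(ev, hyp)
#' @export
rate_by_state <- function(events, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  states <- VIGILANCE_STATES
  minutes <- vapply(states, function(s)
    sum(hyp$labels == s) * hyp$epoch_s / 60, numeric(1))
  n <- vapply(states, function(s) {
    if (is.null(events) || nrow(events) == 0L) 0L
    else sum(events$state == s)
  }, integer(1))
  rate <- ifelse(minutes > 0, n / minutes, NA_real_)
  data.frame(state = states, n_events = n, minutes = minutes, rate = rate,
             row.names = NULL, stringsAsFactors = FALSE)
}

# NREM episodes classified by successor state, excluding the final
# (successor-less) episode; optional minimum duration.
nrem_episodes_by_successor <- function(episodes, successor,
                                       min_episode_s = 0) {
  ep <- episodes[episodes$state == "NREM" & !is.na(episodes$successor) &
                   episodes$successor == successor &
                   (episodes$end - episodes$start) >= min_episode_s, ,
                 drop = FALSE]
  ep
}

#' Episode spindle rates split by successor state
#'
#' Pools events over all NREM episodes that end in REM (N2R) and all that end
#' in wake (N2W); each bucket's rate is total events divided by total episode
#' minutes. The final episode of the recording (no successor) is excluded.
#'
#' @param events Data.frame with \code{start_s}.
#' @param episodes Episode table from \code{\link{extract_episodes}}.
#' @param min_episode_s Minimum NREM episode duration (s) to classify
#'   (default 0, strict).
#' @return List with \code{rate_n2r}, \code{rate_n2w} (events per minute),
#'   \code{n_n2r}, \code{n_n2w} (episode counts), \code{minutes_n2r},
#'   \code{minutes_n2w}.
#' @export
episode_rates_by_successor <- function(events, episodes, min_episode_s = 0) {
  out <- list()
  any_ep <- FALSE
  for (succ in c("REM", "WAKE")) {
    key <- if (succ == "REM") "n2r" else "n2w"
    ep <- nrem_episodes_by_successor(episodes, succ, min_episode_s)
    n_ev <- 0L
    mins <- 0
    if (nrow(ep) > 0L) {
      any_ep <- TRUE
      for (i in seq_len(nrow(ep)))
        n_ev <- n_ev + events_in_window(events, ep$start[i], ep$end[i])
      mins <- sum(ep$end - ep$start) / 60
    }
    out[[paste0("rate_", key)]] <- if (mins > 0) n_ev / mins else NA_real_
    out[[paste0("n_", key)]] <- nrow(ep)
    out[[paste0("minutes_", key)]] <- mins
  }
  if (!any_ep) stop("no NREM episodes with a REM or WAKE successor")
  out
}

#' Event rate in incremental windows before a state transition
#'
#' For each window length (default 5 to 40 s in 5-s steps), computes the
#' event rate in the final window of every NREM episode that transitions into
#' \code{target_state}. Windows are clipped to the episode start (no bleed
#' into the preceding state); clipped windows contribute their actual covered
#' minutes to the pooled denominator.
#'
#' @param events Data.frame with \code{start_s}.
#' @param episodes Episode table from \code{\link{extract_episodes}}.
#' @param target_state Successor state defining the transition
#'   (\code{"REM"} or \code{"WAKE"}).
#' @param windows Strictly increasing window lengths in seconds.
#' @return Object of class \code{transition_profile}: \code{target_state},
#'   \code{windows} (s), \code{rates} (events per minute per window),
#'   \code{n_transitions}.
#' @export
pre_transition_profile <- function(events, episodes, target_state = "REM",
                                   windows = seq(5, 40, by = 5)) {
  target_state <- match.arg(target_state, VIGILANCE_STATES)
  windows <- as.numeric(windows)
  if (length(windows) == 0L || any(diff(windows) <= 0) || any(windows <= 0))
    stop("windows must be positive and strictly increasing")
  ep <- nrem_episodes_by_successor(episodes, target_state)
  if (nrow(ep) == 0L) stop("no NREM transitions into ", target_state)
  rates <- vapply(windows, function(w) {
    n_ev <- 0L
    mins <- 0
    for (i in seq_len(nrow(ep))) {
      t0 <- max(ep$start[i], ep$end[i] - w)
      n_ev <- n_ev + events_in_window(events, t0, ep$end[i])
      mins <- mins + (ep$end[i] - t0) / 60
    }
    if (mins > 0) n_ev / mins else NA_real_
  }, numeric(1))
  structure(list(target_state = target_state, windows = windows,
                 rates = rates, n_transitions = nrow(ep)),
            class = "transition_profile")
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("<transition_profile> into %s over %d transitions\n",
              x$target_state, x$n_transitions))
  print(data.frame(window_s = x$windows,
                   rate_per_min = round(x$rates, 3)), row.names = FALSE)
  invisible(x)
}

#' Moving-window NREM event rate
#'
#' Event rate in a slow moving window (default 30 min long, 25 min overlap,
#' i.e. 5-min steps): per window, NREM-state events divided by NREM minutes
#' inside the window. Windows with under one minute of NREM are flagged and
#' get an \code{NA} rate.
#'
#' @param events Data.frame with \code{start_s} and \code{state}.
#' @param hyp A \code{hypnogram} at least one window long.
#' @param window_min,overlap_min Window length and overlap in minutes.
#' @return Data.frame with \code{t_start_min}, \code{t_mid_min},
#'   \code{nrem_min}, \code{n_events}, \code{rate}, \code{flagged}.
#' @export
moving_window_rate <- function(events, hyp, window_min = 30,
                               overlap_min = 25) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (overlap_min >= window_min) stop("need overlap_min < window_min")
  total_min <- hypnogram_duration(hyp) / 60
  if (total_min < window_min) stop("recording shorter than one window")
  step <- window_min - overlap_min
  starts <- seq(0, total_min - window_min, by = step)
  ep_t <- (seq_along(hyp$labels) - 1) * hyp$epoch_s / 60
  nrem_ev <- if (is.null(events) || nrow(events) == 0L)
    events else events[events$state == "NREM", , drop = FALSE]
  rows <- lapply(starts, function(s0) {
    s1 <- s0 + window_min
    in_win <- ep_t >= s0 & ep_t < s1
    nrem_min <- sum(hyp$labels[in_win] == "NREM") * hyp$epoch_s / 60
    n_ev <- events_in_window(nrem_ev, s0 * 60, s1 * 60)
    flagged <- nrem_min < 1
    data.frame(t_start_min = s0, t_mid_min = s0 + window_min / 2,
               nrem_min = nrem_min, n_events = n_ev,
               rate = if (flagged) NA_real_ else n_ev / nrem_min,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Compare two rate series or scalar summaries
#'
#' Paired per-window differences plus a ratio summary; purely descriptive (no
#' inferential statistics).
#'
#' @param rate_a,rate_b Aligned numeric rate series (or scalars); e.g.
#'   baseline vs recovery epochs.
#' @return List with \code{diff} (\code{rate_b - rate_a}), \code{mean_a},
#'   \code{mean_b}, \code{mean_diff}, and \code{ratio}
#'   (\code{mean_b / mean_a}).
#' @export
compare_epochs <- function(rate_a, rate_b) {
  rate_a <- as.numeric(rate_a); rate_b <- as.numeric(rate_b)
  if (length(rate_a) != length(rate_b))
    stop("rate series have different lengths")
  ma <- mean(rate_a, na.rm = TRUE)
  mb <- mean(rate_b, na.rm = TRUE)
  list(diff = rate_b - rate_a, mean_a = ma, mean_b = mb,
       mean_diff = mb - ma,
       ratio = if (ma != 0) mb / ma else NA_real_)
}
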