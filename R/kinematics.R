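# From raw tracks to the masked, binned, z-scored series every downstream
# analysis consumes.

#' Smooth a position track with a centered 5-point moving average
#'
#' Applied independently to x and y. Edges use a shrinking (truncated)
#' window so the output has the same length and no phase shift.
#'
#' @param track a [position_track()].
#' @param k window length in samples (odd; default 5).
#' @return a smoothed [position_track()].
#' @export
smooth_positions <- function(track, k = 5L) {
  stopifnot(inherits(track, "position_track"), k %% 2 == 1)
  n <- length(track$x)
  if (n < k) stop("track shorter than the smoothing window")
  track$x <- boxcar_truncated(track$x, k)
  track$y <- boxcar_truncated(track$y, k)
  track
}

# Centered boxcar with edge truncation (window shrinks near the ends).
boxcar_truncated <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Instantaneous speed from a (smoothed) position track
#'
#' Speed between successive samples: Euclidean displacement divided by the
#' sampling period, in cm/s. Output has one fewer sample than the track,
#' with timestamps at the interval midpoints and an all-true validity mask
#' (see [mask_epochs()]).
#'
#' @param track a [position_track()], normally after [smooth_positions()].
#' @return a `speed_series` list: `timestamps`, `speed`, `valid`.
#' @export
compute_speed <- function(track) {
  stopifnot(inherits(track, "position_track"))
  dx <- diff(track$x)
  dy <- diff(track$y)
  sp <- sqrt(dx^2 + dy^2) / track$dt
  ts <- track$timestamps[-length(track$timestamps)] + track$dt / 2
  structure(list(timestamps = ts, speed = sp,
                 valid = rep(TRUE, length(sp)), dt = track$dt),
            class = "speed_series")
}

#' Restrict a speed series to task epochs and plausible speeds
#'
#' A sample is valid iff its time lies inside some trial interval
#' (half-open) AND its speed is strictly positive and at most `max_speed`.
#' Zero speed and speeds above `max_speed` indicate position mistracking.
#'
#' @param speed a `speed_series` from [compute_speed()].
#' @param trials a [trial_table()].
#' @param max_speed cm/s; samples above it are masked out (default 60).
#' @return the speed series with `valid` updated.
#' @export
mask_epochs <- function(speed, trials, max_speed = 60) {
  stopifnot(inherits(speed, "speed_series"))
  if (!nrow(trials)) stop("empty trial table")
  in_trial <- rep(FALSE, length(speed$timestamps))
  idx <- findInterval(speed$timestamps, trials$t_start)
  ok <- idx >= 1
  in_trial[ok] <- speed$timestamps[ok] < trials$t_end[idx[ok]]
  speed$valid <- in_trial & speed$speed > 0 & speed$speed <= max_speed
  speed
}

# Contiguous runs of valid samples -> data.frame(start_idx, end_idx).
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Bin speed and one unit's firing rate on a common overlapping-window grid
#'
#' Windows of `bin_s` seconds advance by `bin_s - overlap_s` within each
#' contiguous run of valid samples; windows never cover an invalid sample
#' and never bridge two runs, so speed and rate live on an identical grid.
#' `speed_binned` is the window mean of speed; `rate_binned` is the spike
#' count in the window divided by `bin_s`. Each bin carries the id of its
#' contiguous segment so that lagged correlations can avoid mixing across
#' discontinuities.
#'
#' @param speed a masked `speed_series`.
#' @param unit a [spike_train()].
#' @param bin_s window length in seconds (default 1).
#' @param overlap_s window overlap in seconds (default 0.9, i.e. 0.1-s
#'   stride); 0 gives disjoint bins.
#' @return a `binned_pair` list: `bin_centers`, `speed_binned`,
#'   `rate_binned`, `segment`, `trial_id`, `bin_s`, `stride`; zero-length
#'   fields if no window fits.
#' @export
bin_pair <- function(speed, unit, bin_s = 1.0, overlap_s = 0.9) {
  stopifnot(inherits(speed, "speed_series"), overlap_s < bin_s)
  stride <- bin_s - overlap_s
  runs <- valid_runs(speed$valid)
  starts <- numeric(0); seg <- integer(0)
  if (nrow(runs)) for (i in seq_len(nrow(runs))) {
    t0 <- speed$timestamps[runs$start[i]] - speed$dt / 2
    t1 <- speed$timestamps[runs$end[i]] + speed$dt / 2
    nw <- floor((t1 - t0 - bin_s) / stride + 1e-9) + 1
    if (nw < 1) next
    starts <- c(starts, t0 + (seq_len(nw) - 1) * stride)
    seg <- c(seg, rep.int(i, nw))
  }
  if (!length(starts)) {
    return(structure(list(bin_centers = numeric(0), speed_binned = numeric(0),
                          rate_binned = numeric(0), segment = integer(0),
                          trial_id = integer(0), bin_s = bin_s,
                          stride = stride, dt = speed$dt,
                          unit_id = unit$unit_id),
                     class = "binned_pair"))
  }
  ends <- starts + bin_s
  # window mean of speed over samples whose timestamps fall in the window
  idx_lo <- findInterval(starts, speed$timestamps, left.open = TRUE) + 1L
  idx_hi <- findInterval(ends - 1e-12, speed$timestamps)
  cs <- cumsum(c(0, speed$speed))
  sp <- (cs[idx_hi + 1L] - cs[idx_lo]) / (idx_hi - idx_lo + 1L)
  # spike count in [start, end)
  st <- unit$spike_times
  rate <- (findInterval(ends - 1e-12, st) - findInterval(starts, st,
           left.open = TRUE)) / bin_s
  structure(list(bin_centers = starts + bin_s / 2, speed_binned = sp,
                 rate_binned = rate, segment = seg,
                 trial_id = integer(length(starts)), bin_s = bin_s,
                 stride = stride, dt = speed$dt, unit_id = unit$unit_id),
            class = "binned_pair")
}

# Tag each bin with the trial containing its window start (windows may
# bridge two back-to-back trials; the start decides). The probe time sits
# half a sample inside the window so run-leading bins land in their trial.
tag_trials <- function(pair, trials) {
  t0 <- pair$bin_centers - pair$bin_s / 2 + pair$dt / 2
  idx <- findInterval(t0 + 1e-12, trials$t_start)
  tid <- rep(NA_integer_, length(t0))
  ok <- idx >= 1
  ok[ok] <- t0[ok] < trials$t_end[idx[ok]]
  tid[ok] <- trials$trial_id[idx[ok]]
  pair$trial_id <- tid
  pair
}

#' z-score both series of a binned pair
#'
#' Uses the population (n-denominator) standard deviation so that the
#' lagged cross-correlation equals the Pearson correlation coefficient.
#'
#' @param pair a `binned_pair`.
#' @return a `zscored_pair` with `rate_z`, `speed_z` and the grid fields.
#' @export
zscore_pair <- function(pair) {
  stopifnot(inherits(pair, "binned_pair"))
  if (!length(pair$rate_binned)) stop("empty binned pair")
  ssd <- sd_pop(pair$speed_binned)
  rsd <- sd_pop(pair$rate_binned)
  if (ssd == 0 || rsd == 0)
    stop("degenerate unit: zero-variance series cannot be z-scored")
  out <- pair
  out$speed_z <- (pair$speed_binned - mean(pair$speed_binned)) / ssd
  out$rate_z <- (pair$rate_binned - mean(pair$rate_binned)) / rsd
  class(out) <- c("zscored_pair", "binned_pair")
  out
}

#' Filter units by mean in-task firing rate
#'
#' Mean rate is the spike count within trial epochs divided by total trial
#' time; units at or below `min_rate` are excluded (strict inequality).
#'
#' @param units list of [spike_train()] objects.
#' @param trials a [trial_table()].
#' @param min_rate Hz (default 0.5).
#' @return list with `included` (spike trains) and `excluded`
#'   (data.frame unit_id, rate_hz).
#' @export
filter_units <- function(units, trials, min_rate = 0.5) {
  total_t <- sum(trials$t_end - trials$t_start)
  rate <- vapply(units, function(u) {
    n_in <- sum(findInterval(trials$t_end - 1e-12, u$spike_times) -
                findInterval(trials$t_start, u$spike_times, left.open = TRUE))
    n_in / total_t
  }, numeric(1))
  keep <- rate > min_rate
  list(included = units[keep],
       excluded = data.frame(
         unit_id = vapply(units[!keep], `[[`, character(1), "unit_id"),
         rate_hz = rate[!keep]))
}
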