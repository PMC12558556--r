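# Locomotion onset/offset detection and event-aligned normalized PSTHs.

#' Resample a speed series onto a 0.1-s grid
#'
#' Within each contiguous run of valid samples, speed is averaged into
#' 0.1-s bins from the run start (partial trailing bins dropped). Bins keep
#' their run id so windows never bridge masked gaps.
#'
#' @param speed a masked `speed_series`.
#' @param bin_s resampling bin in seconds (default 0.1).
#' @return data.frame: `time` (bin start), `speed`, `segment`.
#' @export
resample_speed <- function(speed, bin_s = 0.1) {
  runs <- valid_runs(speed$valid)
  out <- list()
  cs <- cumsum(c(0, speed$speed))
  for (i in seq_len(nrow(runs))) {
    t0 <- speed$timestamps[runs$start[i]] - speed$dt / 2
    t1 <- speed$timestamps[runs$end[i]] + speed$dt / 2
    nb <- floor((t1 - t0) / bin_s + 1e-9)
    if (nb < 1) next
    starts <- t0 + (seq_len(nb) - 1) * bin_s
    lo <- findInterval(starts, speed$timestamps, left.open = TRUE) + 1L
    hi <- findInterval(starts + bin_s - 1e-12, speed$timestamps)
    out[[length(out) + 1L]] <- data.frame(
      time = starts,
      speed = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L),
      segment = i)
  }
  if (!length(out))
    return(data.frame(time = numeric(0), speed = numeric(0),
                      segment = integer(0)))
  do.call(rbind, out)
}

#' Detect locomotion onset and offset events
#'
#' Scans 7-second windows (2-s pre + 5-s post, advancing by one 0.1-s
#' sample) over each contiguous segment of the resampled speed. An onset
#' requires every pre-window sample strictly below `v_thresh` and at least
#' 50% of post-window samples strictly above it; an offset is the mirror
#' condition. Overlapping candidates resolve to the earliest, and the scan
#' resumes after the accepted window, so events of one kind are at least
#' 7 s apart. `t_ref` is the pre/post boundary (time zero of the PSTH).
#'
#' @param rs resampled speed from [resample_speed()] (0.1-s grid).
#' @param kind `"onset"` or `"offset"`.
#' @param v_thresh threshold in cm/s (default 5).
#' @param pre_s,post_s window parts in seconds (defaults 2 and 5).
#' @return data.frame: `kind`, `t_ref` (seconds); zero rows if none.
#' @export
detect_bouts <- function(rs, kind = c("onset", "offset"), v_thresh = 5,
                         pre_s = 2, post_s = 5) {
  kind <- match.arg(kind)
  bin_s <- 0.1
  npre <- round(pre_s / bin_s); npost <- round(post_s / bin_s)
  win <- npre + npost
  refs <- numeric(0)
  for (sg in unique(rs$segment)) {
    v <- rs$speed[rs$segment == sg]
    tt <- rs$time[rs$segment == sg]
    n <- length(v)
    if (n < win) next
    below <- v < v_thresh
    above <- v > v_thresh
    pre_ok_v <- if (kind == "onset") below else above
    post_cnt_v <- if (kind == "onset") above else below
    cs_pre <- cumsum(c(0, pre_ok_v))
    cs_post <- cumsum(c(0, post_cnt_v))
    i <- 1L
    while (i <= n - win + 1L) {
      pre_all <- (cs_pre[i + npre] - cs_pre[i]) == npre
      post_frac <- (cs_post[i + win] - cs_post[i + npre]) / npost
      if (pre_all && post_frac >= 0.5) {
        refs <- c(refs, tt[i] + pre_s)
        i <- i + win              # resume after the accepted window
      } else i <- i + 1L
    }
  }
  data.frame(kind = rep(kind, length(refs)), t_ref = refs)
}

#' Event-aligned normalized PSTH with its average speed trace
#'
#' For each event, spikes in \[t_ref - 2, t_ref + 5) are histogrammed in
#' 0.1-s bins and converted to rates; each event's histogram is divided by
#' its own mean rate across the window, so its bin-mean is exactly 1.
#' Events with zero spikes in the window are excluded (normalization
#' undefined) and counted. The event-average and SEM are returned per bin,
#' together with the mean speed trace over the same events.
#'
#' @param unit a [spike_train()].
#' @param events data.frame from [detect_bouts()].
#' @param rs resampled speed (for the speed trace); optional.
#' @param pre_s,post_s,bin_s window geometry (defaults 2, 5, 0.1).
#' @return a `psth` list: `bin_centers` (s rel. t_ref), `norm_rate`, `sem`,
#'   `n_events`, `n_excluded`, and `speed_mean`/`speed_sem` when `rs` is
#'   given; `NULL` (empty-PSTH signal) when every event is excluded.
#' @export
event_psth <- function(unit, events, rs = NULL, pre_s = 2, post_s = 5,
                       bin_s = 0.1) {
  stopifnot(nrow(events) >= 1)
  nb <- round((pre_s + post_s) / bin_s)
  edges_rel <- -pre_s + (0:nb) * bin_s
  mats <- matrix(NA_real_, nrow = nrow(events), ncol = nb)
  for (e in seq_len(nrow(events))) {
    edges <- events$t_ref[e] + edges_rel
    cnt <- diff(findInterval(edges - 1e-12, unit$spike_times))
    mats[e, ] <- cnt / bin_s
  }
  total <- rowSums(mats)
  keep <- total > 0
  n_exc <- sum(!keep)
  if (!any(keep)) return(NULL)
  m <- mats[keep, , drop = FALSE]
  m <- m / rowMeans(m)
  out <- list(bin_centers = edges_rel[-1] - bin_s / 2,
              norm_rate = colMeans(m),
              sem = apply(m, 2, sem),
              n_events = sum(keep), n_excluded = n_exc)
  if (!is.null(rs)) {
    sp <- matrix(NA_real_, nrow = nrow(events), ncol = nb)
    for (e in seq_len(nrow(events))) {
      rel <- events$t_ref[e] + out$bin_centers
      idx <- match(round((rel - bin_s / 2) * 1e6), round(rs$time * 1e6))
      ok <- !is.na(idx)
      sp[e, ok] <- rs$speed[idx[ok]]
    }
    out$speed_mean <- colMeans(sp, na.rm = TRUE)
    out$speed_sem <- apply(sp, 2, sem)
  }
  class(out) <- "psth"
  out
}

#' Bout PSTHs for every unit of a session
#'
#' Detects onsets and offsets on the masked, 0.1-s-resampled speed and
#' builds each unit's normalized PSTH for both kinds.
#'
#' @param bundle a [session_bundle()].
#' @param max_speed mask threshold, cm/s.
#' @param v_thresh bout threshold, cm/s.
#' @return long data.frame: unit_id, kind, bin_center, norm_rate, sem,
#'   n_events, plus the session speed trace columns.
#' @export
bout_psth_session <- function(bundle, max_speed = 60, v_thresh = 5) {
  sp <- session_speed(bundle, max_speed = max_speed)
  rs <- resample_speed(sp)
  ev <- rbind(detect_bouts(rs, "onset", v_thresh = v_thresh),
              detect_bouts(rs, "offset", v_thresh = v_thresh))
  rows <- list()
  for (u in bundle$units) for (k in c("onset", "offset")) {
    evk <- ev[ev$kind == k, , drop = FALSE]
    if (!nrow(evk)) next
    p <- event_psth(u, evk, rs = rs)
    if (is.null(p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      unit_id = u$unit_id, kind = k, bin_center = p$bin_centers,
      norm_rate = p$norm_rate, sem = p$sem, n_events = p$n_events,
      speed_mean = p$speed_mean, speed_sem = p$speed_sem)
  }
  if (!length(rows))
    return(data.frame(unit_id = character(0), kind = character(0),
                      bin_center = numeric(0), norm_rate = numeric(0),
                      sem = numeric(0), n_events = integer(0),
                      speed_mean = numeric(0), speed_sem = numeric(0)))
  do.call(rbind, rows)
}
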