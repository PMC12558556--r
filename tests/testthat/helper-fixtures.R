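# Shared fixtures and independent oracles.

# Gapless z-scored pair built directly on the analysis grid (stride 0.1 s),
# bypassing the binning path, for oracle comparisons.
make_zpair <- function(rate, speed, stride = 0.1) {
  zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  structure(list(rate_z = zs(rate), speed_z = zs(speed),
                 segment = rep(1L, length(rate)), stride = stride,
                 bin_s = 1.0, bin_centers = seq_along(rate) * stride),
            class = c("zscored_pair", "binned_pair"))
}

# Brute-force lagged Pearson oracle: explicit shift, trim, cor() per lag.
bf_ccg <- function(rate, speed, max_k) {
  sapply(-max_k:max_k, function(k) {
    L <- length(rate)
    if (k >= 0) {
      x <- rate[(1 + k):L]; y <- speed[1:(L - k)]
    } else {
      x <- rate[1:(L + k)]; y <- speed[(1 - k):L]
    }
    stats::cor(x, y)
  })
}

# Exhaustive bout-window oracle: direct condition evaluation at every
# window start, earliest-candidate resolution, scan resuming after an
# accepted window.
bf_bouts <- function(v, tt, kind, v_thresh = 5, npre = 20L, npost = 50L) {
  n <- length(v)
  refs <- numeric(0)
  i <- 1L
  while (i <= n - (npre + npost) + 1L) {
    pre <- v[i:(i + npre - 1L)]
    post <- v[(i + npre):(i + npre + npost - 1L)]
    hit <- if (kind == "onset")
      all(pre < v_thresh) && mean(post > v_thresh) >= 0.5
    else
      all(pre > v_thresh) && mean(post < v_thresh) >= 0.5
    if (hit) {
      refs <- c(refs, tt[i] + npre * 0.1)
      i <- i + npre + npost
    } else i <- i + 1L
  }
  refs
}

# Resampled-speed data.frame on a clean 0.1-s grid (single segment).
make_rs <- function(v) {
  data.frame(time = (seq_along(v) - 1) * 0.1, speed = v, segment = 1L)
}

# Tiny valid session: constant-ish speed, a few trials, simple units.
tiny_session <- function(seed = 1, duration = 200, n_trials = 12,
                         units = list(unit_spec(5, gain = 0.17,
                                                cell_type = "MSN"))) {
  generate_session(synth_config(duration = duration, n_trials = n_trials,
                                seed = seed, units = units))
}

# A hand-built position track moving at constant speed vx cm/s along x.
line_track <- function(n = 200, dt = 0.1, vx = 10) {
  position_track((0:(n - 1)) * dt, (0:(n - 1)) * dt * vx, rep(0, n), dt = dt)
}
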