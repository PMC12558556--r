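# Ground-truth session generator: bout-structured speed profiles, labeled
# trials, and speed-coupled inhomogeneous-Poisson spike trains.

#' Specification of one synthetic unit
#'
#' The firing intensity is `lambda(t) = softplus(softplus_inv(baseline_rate)
#' + gain * speed(t - coupling_lag) + label offsets)`. The softplus link
#' keeps rates non-negative by construction while staying near-linear in
#' the operating range, so the injected rate-speed correlation is
#' controllable.
#'
#' @param baseline_rate Hz at zero speed (> 0).
#' @param gain Hz per (cm/s); negative values give negatively tuned units.
#' @param coupling_lag seconds; positive means the rate follows speed.
#' @param cell_type `"MSN"` or `"FSI"`.
#' @param label_modulation optional named list mapping
#'   `"cue:<level>"`, `"choice:<level>"` or `"outcome:<level>"` to an
#'   additive Hz offset applied (inside the softplus argument) within
#'   trials of that state.
#' @return a `unit_spec` list.
#' @export
unit_spec <- function(baseline_rate, gain = 0, coupling_lag = 0,
                      cell_type = c("MSN", "FSI"),
                      label_modulation = NULL) {
  cell_type <- match.arg(cell_type)
  stopifnot(baseline_rate > 0)
  structure(list(baseline_rate = baseline_rate, gain = gain,
                 coupling_lag = coupling_lag, cell_type = cell_type,
                 label_modulation = label_modulation),
            class = "unit_spec")
}

#' Synthetic session configuration
#'
#' Defaults emulate a T-maze-like session: speed alternating between near-
#' stationary stops (~1 cm/s) and runs (~20 cm/s) with Ornstein-Uhlenbeck
#' jitter, trials tiling the session with short inter-trial gaps, cue
#' identity alternating in blocks, and occasional tracking artifacts
#' (frozen position giving zero speed, or jumps giving speeds above
#' 60 cm/s).
#'
#' @param duration session length in seconds.
#' @param dt position sampling period (default 0.0256 s).
#' @param n_trials number of trials tiling the session.
#' @param trial_gap_s inter-trial gap in seconds.
#' @param cue_block_len trials per alternating cue block.
#' @param p_rewarded probability a trial is rewarded.
#' @param run_speed mean run speed in cm/s.
#' @param stop_speed mean stop speed in cm/s.
#' @param run_dur_s,stop_dur_s mean state durations in seconds.
#' @param speed_sd OU stationary SD of speed within a state, cm/s.
#' @param ou_tau_s OU time constant in seconds.
#' @param heading_sd heading random-walk SD in rad/sqrt(s).
#' @param artifact_rate mistracking events per minute.
#' @param units list of [unit_spec()] objects.
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(duration = 600, dt = 0.0256, n_trials = 40,
                         trial_gap_s = 1, cue_block_len = 10,
                         p_rewarded = 0.75, run_speed = 20, stop_speed = 1,
                         run_dur_s = 5, stop_dur_s = 3, speed_sd = 2,
                         ou_tau_s = 0.5, heading_sd = 0.3,
                         artifact_rate = 0.5,
                         units = list(unit_spec(5, gain = 0.13)),
                         seed = 1L) {
  stopifnot(duration > 0, n_trials >= 1, run_speed > 0, run_dur_s > 0,
            stop_dur_s > 0, speed_sd > 0)
  if (duration < n_trials * (trial_gap_s + 2))
    stop("duration too short for n_trials trials of usable length")
  if (duration < run_dur_s + stop_dur_s)
    stop("duration too short for a single stop/run bout")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a bout-structured speed profile and 2-D track
#'
#' A semi-Markov alternation of "stop" and "run" states; within each state
#' speed follows an Ornstein-Uhlenbeck process around the state mean
#' (reflected at zero), and the heading performs a smooth random walk. The
#' velocity series is integrated into X-Y positions. Tracking artifacts
#' are injected as ~0.2-s stretches of frozen position (speed exactly 0)
#' or implausibly large jumps (speed > 60 cm/s); the returned true speed is
#' artifact-free.
#'
#' @param config a [synth_config()].
#' @return list: `track` (a [position_track()]), `true_speed` (cm/s per
#'   inter-sample interval, artifact-free), `state` (`"stop"`/`"run"` per
#'   interval), `transitions` (data.frame kind/time of state switches).
#' @export
generate_speed_profile <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  dt <- config$dt
  n_iv <- floor(config$duration / dt)      # number of velocity intervals
  # state sequence: alternate stop/run, jittered durations (>= 1 s)
  t <- 0; state <- "stop"
  states <- character(0); lens <- integer(0)
  while (t < config$duration) {
    mu_d <- if (state == "run") config$run_dur_s else config$stop_dur_s
    d <- max(1, rnorm(1, mu_d, 0.25 * mu_d))
    len <- min(round(d / dt), n_iv - sum(lens))
    if (len <= 0) break
    states <- c(states, state); lens <- c(lens, len)
    t <- t + len * dt
    state <- if (state == "run") "stop" else "run"
  }
  if (sum(lens) < n_iv) { lens[length(lens)] <- lens[length(lens)] + n_iv - sum(lens) }
  state_iv <- rep(states, lens)
  mu <- ifelse(state_iv == "run", config$run_speed, config$stop_speed)
  # OU speed around the state mean, reflected at zero
  a <- exp(-dt / config$ou_tau_s)
  innov_sd <- config$speed_sd * sqrt(1 - a^2)
  v <- numeric(n_iv)
  v[1] <- mu[1]
  eps <- rnorm(n_iv, 0, innov_sd)
  for (i in 2:n_iv) v[i] <- mu[i] + a * (v[i - 1] - mu[i]) + eps[i]
  v <- abs(v)
  # transitions of the true state sequence
  ends <- cumsum(lens)
  tr_idx <- ends[-length(ends)]
  transitions <- data.frame(
    kind = ifelse(states[-1] == "run", "onset", "offset"),
    time = tr_idx * dt)
  # integrate to positions with a smooth random heading
  theta <- cumsum(rnorm(n_iv, 0, config$heading_sd * sqrt(dt)))
  disp_x <- v * dt * cos(theta)
  disp_y <- v * dt * sin(theta)
  # artifacts: blocks of ~8 samples, frozen (speed 0) or jump (90 cm/s)
  n_art <- rpois(1, config$artifact_rate * config$duration / 60)
  art_len <- 8L
  if (n_art > 0) {
    for (j in seq_len(n_art)) {
      i0 <- sample.int(n_iv - art_len, 1)
      idx <- i0:(i0 + art_len - 1L)
      if (runif(1) < 0.5) {
        disp_x[idx] <- 0; disp_y[idx] <- 0
      } else {
        disp_x[idx] <- 90 * dt * cos(theta[idx])
        disp_y[idx] <- 90 * dt * sin(theta[idx])
      }
    }
  }
  x <- cumsum(c(0, disp_x)); y <- cumsum(c(0, disp_y))
  ts <- (0:n_iv) * dt
  list(track = position_track(ts, x, y, dt = dt),
       true_speed = v, state = state_iv, transitions = transitions)
}

#' Generate a labeled trial table tiling the session
#'
#' Trials of equal length separated by `trial_gap_s`; cue alternates in
#' blocks of `cue_block_len` trials, choice is a fair coin, outcome is
#' rewarded with probability `p_rewarded` (with both outcome states forced
#' to occur at least twice).
#'
#' @param config a [synth_config()].
#' @return a [trial_table()].
#' @export
generate_trials <- function(config) {
  n <- config$n_trials
  tl <- (config$duration - n * config$trial_gap_s) / n
  if (tl <= 2) stop("trials too short; reduce n_trials or trial_gap_s")
  t_start <- (seq_len(n) - 1) * (tl + config$trial_gap_s)
  cue <- rep(c("visual", "spatial"),
             each = config$cue_block_len,
             length.out = 2 * n)[seq_len(n)]
  choice <- ifelse(runif(n) < 0.5, "left", "right")
  outcome <- ifelse(runif(n) < config$p_rewarded, "rewarded", "non_rewarded")
  # ensure both states of each binary label occur at least twice
  force_two <- function(x, levels) {
    for (lv in levels) {
      need <- 2 - sum(x == lv)
      if (need > 0) {
        other <- which(x != lv)
        x[sample(other, need)] <- lv
      }
    }
    x
  }
  choice <- force_two(choice, c("left", "right"))
  outcome <- force_two(outcome, c("rewarded", "non_rewarded"))
  trial_table(data.frame(trial_id = seq_len(n), t_start = t_start,
                         t_end = t_start + tl, cue = cue, choice = choice,
                         outcome = outcome))
}

#' Generate one inhomogeneous-Poisson spike train
#'
#' Exact thinning: candidate spikes are drawn homogeneously at the
#' intensity upper bound and accepted with probability
#' `lambda(t) / lambda_max`, where `lambda(t)` is the softplus-rectified
#' speed-coupled intensity of the [unit_spec()] evaluated at the candidate
#' time (speed linearly interpolated, lag applied, label offsets added
#' within matching trials).
#'
#' @param true_speed artifact-free speed per interval (cm/s).
#' @param spec a [unit_spec()].
#' @param dt sampling period of `true_speed`.
#' @param trials a [trial_table()] (needed when `label_modulation` is set;
#'   may be `NULL` otherwise).
#' @return a [spike_train()] spanning `[0, length(true_speed) * dt]`.
#' @export
generate_spike_train <- function(true_speed, spec, dt = 0.0256,
                                 trials = NULL) {
  stopifnot(inherits(spec, "unit_spec"), all(is.finite(true_speed)))
  T_end <- length(true_speed) * dt
  t_mid <- (seq_along(true_speed) - 0.5) * dt
  b <- softplus_inv(spec$baseline_rate)
  max_off <- if (is.null(spec$label_modulation)) 0 else
    max(0, unlist(spec$label_modulation))
  lam_max <- softplus(b + max(0, spec$gain * max(true_speed),
                              spec$gain * min(true_speed)) + max_off) + 1e-6
  n_cand <- rpois(1, lam_max * T_end)
  if (n_cand == 0)
    return(spike_train(paste0("synth-", spec$cell_type), numeric(0),
                       spec$cell_type))
  tc <- sort(runif(n_cand, 0, T_end))
  s_lag <- approx(t_mid, true_speed, xout = tc - spec$coupling_lag,
                  rule = 2)$y
  eta <- b + spec$gain * s_lag
  if (!is.null(spec$label_modulation)) {
    stopifnot(!is.null(trials))
    for (key in names(spec$label_modulation)) {
      kv <- strsplit(key, ":", fixed = TRUE)[[1]]
      stopifnot(length(kv) == 2, kv[1] %in% c("cue", "choice", "outcome"))
      sel <- trials[[kv[1]]] == kv[2]
      idx <- findInterval(tc, trials$t_start)
      in_state <- idx >= 1 & idx <= nrow(trials)
      in_state[in_state] <- tc[in_state] < trials$t_end[idx[in_state]] &
        sel[idx[in_state]]
      eta[in_state] <- eta[in_state] + spec$label_modulation[[key]]
    }
  }
  keep <- runif(n_cand) < softplus(eta) / lam_max
  spike_train(paste0("synth-", spec$cell_type), tc[keep], spec$cell_type)
}

#' Generate a complete synthetic session with ground truth
#'
#' Seeds the RNG from `config$seed`, draws the speed profile, the trial
#' table and one spike train per [unit_spec()], and returns both the
#' analysis-facing [session_bundle()] and a separate ground-truth record
#' (unit parameters, true bout transition times, artifact-free speed) that
#' is never consumed by the analysis code.
#'
#' @param config a [synth_config()].
#' @return list with elements `bundle` and `truth`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  prof <- generate_speed_profile(config)
  trials <- generate_trials(config)
  units <- vector("list", length(config$units))
  for (i in seq_along(config$units)) {
    u <- generate_spike_train(prof$true_speed, config$units[[i]],
                              dt = config$dt, trials = trials)
    u$unit_id <- sprintf("u%03d", i)
    units[[i]] <- u
  }
  bundle <- session_bundle(prof$track, units, trials,
                           session_id = sprintf("synth-seed%d", config$seed))
  truth <- list(
    units = data.frame(
      unit_id = sprintf("u%03d", seq_along(config$units)),
      baseline_rate = vapply(config$units, `[[`, numeric(1), "baseline_rate"),
      gain = vapply(config$units, `[[`, numeric(1), "gain"),
      coupling_lag = vapply(config$units, `[[`, numeric(1), "coupling_lag"),
      cell_type = vapply(config$units, `[[`, character(1), "cell_type")),
    transitions = prof$transitions,
    true_speed = prof$true_speed,
    state = prof$state)
  list(bundle = bundle, truth = truth)
}
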