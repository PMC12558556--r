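# Stability of speed scores across trial blocks / cue / choice / outcome,
# and label-shuffle tests of per-unit firing-rate modulation.

#' Assign contiguous trial blocks
#'
#' Splits the trials, in temporal order, into `n_blocks` near-equal
#' contiguous blocks (remainder trials go to the earliest blocks). If there
#' are too few trials for `n_blocks` blocks of at least `min_per_block`
#' trials, fewer blocks are used, with a warning; below
#' `2 * min_per_block` trials the block analysis is not meaningful and an
#' error of class `stability_skipped` is raised.
#'
#' @param trials a [trial_table()].
#' @param n_blocks target number of blocks (default 5).
#' @param min_per_block minimum trials per block (default 11).
#' @return the trial table with its `block` column filled in.
#' @export
assign_blocks <- function(trials, n_blocks = 5L, min_per_block = 11L) {
  n <- nrow(trials)
  if (n < 2L * min_per_block)
    stop(structure(class = c("stability_skipped", "error", "condition"),
                   list(message = sprintf(
                     "only %d trials; block analysis needs at least %d",
                     n, 2L * min_per_block), call = NULL)))
  b <- min(n_blocks, n %/% min_per_block)
  if (b < n_blocks)
    warning(sprintf("only %d trials; using %d blocks instead of %d",
                    n, b, n_blocks))
  base <- n %/% b
  sizes <- rep(base, b)
  extra <- n - base * b
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  trials$block <- rep(seq_len(b), sizes)
  trials
}

#' Speed score restricted to a subset of trials
#'
#' Identical computation to the full-session score, restricted to bins
#' whose window starts inside a trial of the requested subset; segment
#' bookkeeping is preserved so lagged pairs never mix across
#' discontinuities. With `level = NULL` (or a level covering all trials)
#' this reproduces the session score bit-for-bit.
#'
#' @param bundle a [session_bundle()] (trials must carry `block` labels if
#'   `dimension = "block"`; see [assign_blocks()]).
#' @param unit a [spike_train()].
#' @param dimension one of `"block"`, `"cue"`, `"choice"`, `"outcome"`, or
#'   `"all"`.
#' @param level the selected label value (ignored for `"all"`).
#' @param bin_s,overlap_s,max_speed,max_lag_s,n_min as in [score_session()].
#' @return named numeric `c(score, lag_s, n_bins)`; `score`/`lag_s` are
#'   `NaN` when the subset has too few bins (reason attached as attribute).
#' @export
subset_speed_score <- function(bundle, unit, dimension = "all", level = NULL,
                               bin_s = 1.0, overlap_s = 0.9, max_speed = 60,
                               max_lag_s = 5.0, n_min = 30L) {
  stopifnot(dimension %in% c("all", "block", "cue", "choice", "outcome"))
  sp <- session_speed(bundle, max_speed = max_speed)
  pair <- bin_pair(sp, unit, bin_s = bin_s, overlap_s = overlap_s)
  pair <- tag_trials(pair, bundle$trials)
  keep <- rep(TRUE, length(pair$bin_centers))
  if (dimension != "all") {
    keep <- !is.na(pair$trial_id)
    if (is.null(level)) stop("level required for dimension ", dimension)
    labels <- bundle$trials[[dimension]]
    if (dimension == "block" && all(is.na(labels)))
      stop("trials carry no block labels; run assign_blocks() first")
    sel <- bundle$trials$trial_id[labels == level]
    keep <- keep & pair$trial_id %in% sel
  }
  sub <- pair
  for (f in c("bin_centers", "speed_binned", "rate_binned", "segment",
              "trial_id"))
    sub[[f]] <- pair[[f]][keep]
  res <- tryCatch({
    z <- zscore_pair(sub)
    speed_score(cross_correlogram(z, max_lag_s = max_lag_s, n_min = n_min))
  }, error = function(e) {
    structure(c(score = NaN, lag_s = NaN), reason = conditionMessage(e))
  })
  out <- c(res[1], res[2], n_bins = sum(keep))
  attr(out, "reason") <- attr(res, "reason")
  out
}

#' Stability table for one unit across every subset
#'
#' Convenience wrapper: session score plus scores per block, cue, choice
#' and outcome level.
#'
#' @inheritParams subset_speed_score
#' @return data.frame with columns unit_id, dimension, level, score,
#'   lag_s, n_bins.
#' @export
stability_table <- function(bundle, unit, ...) {
  trials <- bundle$trials
  rows <- list(data.frame(dimension = "all", level = "all"))
  if (!all(is.na(trials$block)))
    rows <- c(rows, list(data.frame(dimension = "block",
                                    level = as.character(sort(unique(trials$block))))))
  for (d in c("cue", "choice", "outcome"))
    rows <- c(rows, list(data.frame(dimension = d,
                                    level = sort(unique(trials[[d]])))))
  grid <- do.call(rbind, rows)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$dimension[i]
    lv <- if (d == "all") NULL else grid$level[i]
    s <- subset_speed_score(bundle, unit, dimension = d, level = lv, ...)
    data.frame(unit_id = unit$unit_id, dimension = d, level = grid$level[i],
               score = s[["score"]], lag_s = s[["lag_s"]],
               n_bins = s[["n_bins"]])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-trial firing rates of one unit
#'
#' In-trial spike count divided by trial duration, for every trial
#' (half-open intervals).
#'
#' @param unit a [spike_train()].
#' @param trials a [trial_table()].
#' @return numeric vector, one rate (Hz) per trial row.
#' @export
trial_rates <- function(unit, trials) {
  st <- unit$spike_times
  counts <- findInterval(trials$t_end - 1e-12, st) -
    findInterval(trials$t_start, st, left.open = TRUE)
  counts / (trials$t_end - trials$t_start)
}

#' Label-shuffle test of firing-rate modulation by a task variable
#'
#' The statistic is the difference in mean per-trial firing rate between
#' the two states of `dimension` (first level minus second, levels in the
#' table's canonical order). The null is built by permuting trial labels
#' without replacement (`n_shuffles` times), preserving per-state trial
#' counts; the unit is called modulated when the observed difference lies
#' more than 2 SD from the surrogate mean.
#'
#' @param unit a [spike_train()].
#' @param trials a [trial_table()].
#' @param dimension `"cue"`, `"choice"` or `"outcome"`.
#' @param n_shuffles label permutations (default 10000).
#' @return one-row data.frame: unit_id, dimension, levels compared,
#'   delta_rate (Hz), surrogate_mean, surrogate_sd, p_emp, is_modulated.
#' @export
modulation_test <- function(unit, trials, dimension = c("cue", "choice",
                                                        "outcome"),
                            n_shuffles = 10000L) {
  dimension <- match.arg(dimension)
  lv <- switch(dimension, cue = c("visual", "spatial"),
               choice = c("left", "right"),
               outcome = c("rewarded", "non_rewarded"))
  lab <- trials[[dimension]]
  nA <- sum(lab == lv[1]); nB <- sum(lab == lv[2])
  if (nA < 2 || nB < 2)
    stop(structure(class = c("test_skipped", "error", "condition"),
                   list(message = sprintf(
                     "fewer than 2 trials in a %s state", dimension),
                     call = NULL)))
  r <- trial_rates(unit, trials)
  isA <- lab == lv[1]
  delta <- mean(r[isA]) - mean(r[!isA])
  n <- length(r)
  # mean_A - mean_B is a linear function of the sum over the permuted A-set
  tot <- sum(r)
  surr <- vapply(seq_len(n_shuffles), function(i) {
    sA <- sum(r[sample.int(n, nA)])
    sA / nA - (tot - sA) / nB
  }, numeric(1))
  mu <- mean(surr); sdv <- stats::sd(surr)
  data.frame(unit_id = unit$unit_id, dimension = dimension,
             level_a = lv[1], level_b = lv[2], delta_rate = delta,
             surrogate_mean = mu, surrogate_sd = sdv,
             p_emp = empirical_p(delta, surr),
             is_modulated = abs(delta - mu) > 2 * sdv)
}
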