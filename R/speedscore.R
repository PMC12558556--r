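# Speed score: signed peak of the lagged correlation between z-scored
# firing rate and z-scored speed; circular-shift surrogate null; BH-FDR;
# sign/strength classification.

#' Cross-correlogram between z-scored rate and speed
#'
#' Pearson correlation at every integer multiple of the bin stride with
#' `|lag| <= max_lag_s`. Positive lag means the rate series follows speed:
#' `r(lag)` correlates `rate(t)` against `speed(t - lag)`. Only bin pairs
#' inside the same contiguous segment contribute; lags with fewer than
#' `n_min` pairs are `NA`.
#'
#' @param z a `zscored_pair` from [zscore_pair()].
#' @param max_lag_s lag search half-window in seconds (default 5).
#' @param n_min minimum overlapping pairs per lag (default 30).
#' @return a `ccg` list: `lags` (s), `r`, `n_pairs`, `stride`.
#' @export
cross_correlogram <- function(z, max_lag_s = 5.0, n_min = 30L) {
  stopifnot(inherits(z, "zscored_pair"))
  max_k <- as.integer(floor(max_lag_s / z$stride + 1e-9))
  out <- ccg_lags_cpp(z$rate_z, z$speed_z, as.integer(z$segment),
                      max_k, as.integer(n_min))
  if (all(is.na(out$r)))
    stop("degenerate unit: fewer than n_min overlapping pairs at every lag")
  structure(list(lags = (-max_k:max_k) * z$stride, r = out$r,
                 n_pairs = out$n_pairs, stride = z$stride),
            class = "ccg")
}

# Peak of |r| carrying its sign; ties on |r| resolved to the lag closest to
# zero, exact ties to the more negative lag.
peak_pick <- function(r, lags) {
  a <- abs(r)
  a[is.na(a)] <- -Inf
  best <- max(a)
  cand <- which(a == best)
  if (length(cand) > 1) {
    d <- abs(lags[cand])
    cand <- cand[d == min(d)]
    cand <- cand[which.min(lags[cand])]
  }
  c(score = r[cand], lag_s = lags[cand])
}

#' Speed score and speed lag from a cross-correlogram
#'
#' The score is the correlation at the lag maximizing `|r|` (so strong
#' negative relationships are reported as negative peaks); the lag is where
#' that peak occurs. Ties on `|r|` go to the lag closest to zero, an exact
#' tie to the more negative lag.
#'
#' @param ccg a `ccg` from [cross_correlogram()].
#' @return named numeric `c(score, lag_s)`.
#' @export
speed_score <- function(ccg) {
  stopifnot(inherits(ccg, "ccg"))
  peak_pick(ccg$r, ccg$lags)
}

#' Circular-shift surrogate speed scores
#'
#' Each surrogate rotates the z-scored rate series through the concatenated
#' valid-bin sequence by a uniform random number of strides between 20% and
#' 50% of the analyzed length (direction random), then recomputes the full
#' lag profile and its signed peak. Rotation preserves the rate series'
#' autocorrelation while destroying its alignment with speed.
#'
#' @param z a `zscored_pair`.
#' @param n_surr number of surrogates (default 10000).
#' @param shift_frac length-2 fraction range of the analyzed length
#'   (default `c(0.2, 0.5)`).
#' @param max_lag_s,n_min as in [cross_correlogram()].
#' @return numeric vector of `n_surr` surrogate scores.
#' @export
surrogate_null <- function(z, n_surr = 10000L, shift_frac = c(0.2, 0.5),
                           max_lag_s = 5.0, n_min = 30L) {
  stopifnot(inherits(z, "zscored_pair"))
  L <- length(z$rate_z)
  max_k <- as.integer(floor(max_lag_s / z$stride + 1e-9))
  if (ceiling(shift_frac[1] * L) < max_k)
    stop("series too short: minimum circular shift is below max_lag")
  shifts <- draw_shifts(n_surr, L, shift_frac)
  rmat <- ccg_shift_matrix_cpp(z$rate_z, z$speed_z, as.integer(z$segment),
                               max_k, as.integer(n_min), shifts)
  lags <- (-max_k:max_k) * z$stride
  apply(rmat, 2, function(r) peak_pick(r, lags)[1])
}

#' Classify one unit against its surrogate distribution
#'
#' A unit is a candidate speed cell when its score lies more than 2
#' surrogate standard deviations from the surrogate mean. The empirical
#' two-sided p-value is also computed so that, across units, the
#' Benjamini-Hochberg procedure can gate the final call (see
#' [score_session()]).
#'
#' @param score,lag_s the unit's speed score and lag.
#' @param surrogates surrogate score vector from [surrogate_null()].
#' @param unit_id,cell_type identifiers carried into the result row.
#' @return one-row data.frame with score, lag, surrogate summary, `p_emp`,
#'   the 2-SD decision (`pass_2sd`), sign and strength class.
#' @export
classify_unit <- function(score, lag_s, surrogates, unit_id = NA,
                          cell_type = NA) {
  if (length(surrogates) < 1000)
    warning("fewer than 1000 surrogates; null summary will be noisy")
  mu <- mean(surrogates)
  sdv <- stats::sd(surrogates)
  if (sdv == 0) stop("degenerate unit: zero surrogate standard deviation")
  data.frame(unit_id = as.character(unit_id),
             cell_type = as.character(cell_type),
             score = unname(score), lag_s = unname(lag_s),
             surrogate_mean = mu, surrogate_sd = sdv,
             p_emp = empirical_p(score, surrogates),
             pass_2sd = abs(score - mu) > 2 * sdv,
             sign = ifelse(score > 0, "positive", "negative"),
             strength = strength_class(score))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values (monotone step-up).
#' @export
fdr_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Strength class of a speed score
#'
#' Thresholds on `|score|`: weak below 0.2, moderate from 0.2 to 0.4,
#' strong above 0.4.
#'
#' @param score numeric vector of speed scores.
#' @return character vector in `{weak, moderate, strong}`.
#' @export
strength_class <- function(score) {
  a <- abs(score)
  ifelse(a < 0.2, "weak", ifelse(a <= 0.4, "moderate", "strong"))
}

#' Score every unit of a session
#'
#' Full per-unit pipeline: mask speed to task epochs, drop low-rate units,
#' bin, z-score, cross-correlate, draw surrogates, classify, and apply the
#' BH correction across units. A unit is a speed cell iff it passes the
#' 2-SD surrogate rule AND its BH-adjusted empirical p is below `alpha`.
#'
#' @param bundle a [session_bundle()].
#' @param bin_s,overlap_s binning grid (defaults 1 s, 0.9 s).
#' @param max_speed mask threshold in cm/s (default 60).
#' @param max_lag_s lag search half-window (default 5 s).
#' @param n_surr surrogates per unit (default 10000).
#' @param alpha significance level (default 0.05).
#' @param min_rate unit inclusion threshold in Hz (default 0.5).
#' @param n_min minimum pairs per lag (default 30).
#' @return data.frame, one row per included unit, with the
#'   [classify_unit()] fields plus `p_fdr` and `is_speed_cell`; excluded or
#'   degenerate units are listed in the `"excluded"` attribute.
#' @export
score_session <- function(bundle, bin_s = 1.0, overlap_s = 0.9,
                          max_speed = 60, max_lag_s = 5.0,
                          n_surr = 10000L, alpha = 0.05,
                          min_rate = 0.5, n_min = 30L) {
  sp <- session_speed(bundle, max_speed = max_speed)
  flt <- filter_units(bundle$units, bundle$trials, min_rate = min_rate)
  excluded <- flt$excluded
  if (nrow(excluded)) excluded$reason <- "low firing rate"
  rows <- list()
  for (u in flt$included) {
    res <- tryCatch({
      z <- zscore_pair(bin_pair(sp, u, bin_s = bin_s, overlap_s = overlap_s))
      ccg <- cross_correlogram(z, max_lag_s = max_lag_s, n_min = n_min)
      pk <- speed_score(ccg)
      surr <- surrogate_null(z, n_surr = n_surr, max_lag_s = max_lag_s,
                             n_min = n_min)
      classify_unit(pk["score"], pk["lag_s"], surr,
                    unit_id = u$unit_id, cell_type = u$cell_type)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- rbind(excluded, data.frame(unit_id = u$unit_id,
                                             rate_hz = NA_real_,
                                             reason = conditionMessage(res)))
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    classify_unit(NA_real_, NA_real_, rnorm(1000))[0, ]
  if (nrow(out)) {
    out$p_fdr <- fdr_adjust(out$p_emp)
    out$is_speed_cell <- out$pass_2sd & out$p_fdr < alpha
  } else {
    out$p_fdr <- numeric(0); out$is_speed_cell <- logical(0)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

# Masked session speed series (smoothed track -> speed -> task mask).
session_speed <- function(bundle, max_speed = 60) {
  mask_epochs(compute_speed(smooth_positions(bundle$position)),
              bundle$trials, max_speed = max_speed)
}
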