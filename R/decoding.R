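# Cross-validated decoding of locomotion speed from firing rates:
# per-unit degree-3 polynomial regression and multi-unit ridge regression,
# with circular-shift chance levels.

#' Disjoint 1-s binned series for decoding
#'
#' Speed and per-unit rates on a common disjoint 1-s grid (no overlap, so
#' contiguous cross-validation folds do not share samples).
#'
#' @param bundle a [session_bundle()].
#' @param max_speed mask threshold, cm/s.
#' @param bin_s bin length (default 1 s).
#' @return list: `speed` (vector), `rates` (matrix bins x units, columns
#'   named by unit id), `segment`, `bin_centers`.
#' @export
decoding_series <- function(bundle, max_speed = 60, bin_s = 1.0) {
  sp <- session_speed(bundle, max_speed = max_speed)
  pairs <- lapply(bundle$units, function(u)
    bin_pair(sp, u, bin_s = bin_s, overlap_s = 0))
  p0 <- pairs[[1]]
  rates <- vapply(pairs, `[[`, numeric(length(p0$rate_binned)),
                  "rate_binned")
  rates <- matrix(rates, ncol = length(pairs))
  colnames(rates) <- vapply(bundle$units, `[[`, character(1), "unit_id")
  list(speed = p0$speed_binned, rates = rates, segment = p0$segment,
       bin_centers = p0$bin_centers)
}

#' Winsorize (upper-tail cap) a series at a percentile
#'
#' Values above the `p` quantile (linear interpolation between order
#' statistics) are replaced by it; the lower tail is untouched. The cap may
#' be supplied (e.g. one fitted on training data only).
#'
#' @param x numeric vector.
#' @param p percentile in (0, 1) (default 0.95).
#' @param cap optional precomputed cap overriding the quantile of `x`.
#' @return capped vector, with the cap as attribute `"cap"`.
#' @export
winsorize_upper <- function(x, p = 0.95, cap = NULL) {
  if (is.null(cap)) cap <- unname(quantile(x, p, type = 7))
  out <- pmin(x, cap)
  attr(out, "cap") <- cap
  out
}

#' Gaussian-smooth a series within segments
#'
#' Kernel SD of `sd_bins` samples, truncated at 4 SD and renormalized at
#' segment edges; applied independently per contiguous segment.
#'
#' @param x numeric vector.
#' @param segment integer segment id per sample.
#' @param sd_bins kernel SD in samples (default 1).
#' @return smoothed vector.
#' @export
gauss_smooth <- function(x, segment = rep(1L, length(x)), sd_bins = 1) {
  h <- ceiling(4 * sd_bins)
  w <- exp(-((-h:h)^2) / (2 * sd_bins^2))
  out <- numeric(length(x))
  for (sg in unique(segment)) {
    idx <- which(segment == sg)
    v <- x[idx]; n <- length(v)
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - h); hi <- min(n, i + h)
      ww <- w[(lo - i + h + 1):(hi - i + h + 1)]
      sm[i] <- sum(ww * v[lo:hi]) / sum(ww)
    }
    out[idx] <- sm
  }
  out
}

#' Prepare decoding series: cap then smooth
#'
#' Applies the 95th-percentile upper cap and the SD = 1 bin Gaussian
#' smoothing to a series, in that order. For leakage-free cross-validation
#' the decoders refit the cap on training folds internally; this function
#' is the whole-series convenience form.
#'
#' @param x numeric vector (one series, e.g. one unit's binned rate).
#' @param segment contiguous-segment ids.
#' @param p cap percentile (default 0.95).
#' @param sd_bins smoothing SD in bins (default 1).
#' @return prepared vector.
#' @export
prepare_decoding_series <- function(x, segment = rep(1L, length(x)),
                                    p = 0.95, sd_bins = 1) {
  gauss_smooth(as.numeric(winsorize_upper(x, p)), segment, sd_bins)
}

# Contiguous 10-fold partition: sizes differ by at most one and cover all
# bins in temporal order.
cv_folds <- function(n, n_folds = 10L) {
  if (n < n_folds) stop("too few bins for ", n_folds, "-fold CV")
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(n_folds), sizes)
}

# Coefficient of determination on held-out data (reference mean = test-set
# mean, so an uninformative predictor scores <= 0).
r2_score <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

# Degree-d polynomial expansion of each column of a rate matrix (per-unit
# powers, no cross-unit interactions).
poly_features <- function(rates, degree = 3L) {
  rates <- as.matrix(rates)
  do.call(cbind, lapply(seq_len(ncol(rates)), function(j)
    vapply(seq_len(degree), function(d) rates[, j]^d,
           numeric(nrow(rates)))))
}

# Shared CV engine. Per fold: fit caps (one per series) and feature
# standardization on the training bins, apply to all bins, smooth within
# segments, expand polynomial features, fit OLS (ridge = 0) or ridge, and
# evaluate held-out R^2.
cv_decode <- function(rates, speed, segment, degree = 3L, n_folds = 10L,
                      ridge = 0, p_cap = 0.95, sd_bins = 1) {
  rates <- as.matrix(rates)
  n <- length(speed)
  fold <- cv_folds(n, n_folds)
  fold_r2 <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    caps <- apply(rates[!test, , drop = FALSE], 2, quantile, probs = p_cap,
                  type = 7)
    rc <- rates
    for (j in seq_len(ncol(rates)))
      rc[, j] <- gauss_smooth(pmin(rates[, j], caps[j]), segment, sd_bins)
    scap <- quantile(speed[!test], p_cap, type = 7)
    y <- gauss_smooth(pmin(speed, scap), segment, sd_bins)
    X <- poly_features(rc, degree)
    mu <- colMeans(X[!test, , drop = FALSE])
    sg <- apply(X[!test, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    ytr <- y[!test]
    Xtr <- Xs[!test, , drop = FALSE]
    if (ridge > 0) {
      XtX <- crossprod(Xtr) + diag(ridge, ncol(Xtr))
      beta <- solve(XtX, crossprod(Xtr, ytr - mean(ytr)))
      yhat <- mean(ytr) + Xs[test, , drop = FALSE] %*% beta
    } else {
      fit <- lm.fit(cbind(1, Xtr), ytr)
      cf <- coef(fit); cf[is.na(cf)] <- 0
      yhat <- cbind(1, Xs[test, , drop = FALSE]) %*% cf
    }
    fold_r2[f] <- r2_score(y[test], as.numeric(yhat))
  }
  fold_r2
}

#' Decode speed from a single unit
#'
#' Degree-3 polynomial features of the unit's prepared rate, ordinary
#' least squares, 10 contiguous unshuffled temporal folds; the decoding
#' accuracy is the mean held-out R^2 (negative values mean worse than the
#' test-fold mean). Winsorization and standardization are fitted on the
#' training folds only.
#'
#' @param rate,speed disjoint 1-s binned series (see [decoding_series()]).
#' @param segment contiguous-segment ids.
#' @param degree polynomial degree (default 3).
#' @param n_folds folds (default 10).
#' @return a `decoding_result` list: `unit_ids`, `r2`, `fold_r2`,
#'   `n_folds`; `r2` is `NaN` for a constant-rate unit.
#' @export
decode_single <- function(rate, speed, segment = rep(1L, length(speed)),
                          degree = 3L, n_folds = 10L) {
  if (sd_pop(rate) == 0) {
    return(structure(list(unit_ids = NA_character_, r2 = NaN,
                          fold_r2 = rep(NaN, n_folds), n_folds = n_folds,
                          reason = "constant rate"),
                     class = "decoding_result"))
  }
  fr <- cv_decode(matrix(rate, ncol = 1), speed, segment, degree = degree,
                  n_folds = n_folds, ridge = 0)
  structure(list(unit_ids = NA_character_, r2 = mean(fr), fold_r2 = fr,
                 n_folds = n_folds),
            class = "decoding_result")
}

#' Chance-level decoding accuracy by circular shifting
#'
#' Repeats [decode_single()] (or the ridge pipeline for several units) on
#' rate series circularly shifted by 20-50% of the analyzed length, one
#' common shift for all units per repetition, and averages the resulting
#' mean R^2 values.
#'
#' @param rates matrix (bins x units) of binned rates.
#' @param speed binned speed.
#' @param segment segment ids.
#' @param n_rep repetitions (default 100).
#' @param shift_frac shift range as fraction of length (default 0.2-0.5).
#' @param degree,n_folds,ridge passed to the CV engine.
#' @return mean surrogate R^2 over repetitions.
#' @export
chance_level <- function(rates, speed, segment = rep(1L, length(speed)),
                         n_rep = 100L, shift_frac = c(0.2, 0.5),
                         degree = 3L, n_folds = 10L, ridge = 0) {
  rates <- as.matrix(rates)
  shifts <- draw_shifts(n_rep, nrow(rates), shift_frac)
  r2s <- vapply(shifts, function(s) {
    sh <- apply(rates, 2, rotate_vec, k = s)
    mean(cv_decode(sh, speed, segment, degree = degree, n_folds = n_folds,
                   ridge = ridge))
  }, numeric(1))
  mean(r2s)
}

#' Multi-unit speed decoding over cell combinations
#'
#' Considers units whose single-unit decoding accuracy is at least
#' `min_r2`, forms every combination of 1 to `max_k` of them, and decodes
#' speed with ridge regression (penalty `ridge` on standardized per-unit
#' degree-3 features, intercept unpenalized) under the same contiguous
#' 10-fold CV.
#'
#' @param rates matrix (bins x units), columns named by unit id.
#' @param speed binned speed.
#' @param segment segment ids.
#' @param single_r2 named vector of single-unit accuracies (from
#'   [decode_single()]); computed internally when `NULL`.
#' @param min_r2 eligibility threshold (default 0.1).
#' @param max_k largest combination size (default 5).
#' @param ridge penalty (default 1).
#' @param degree,n_folds as elsewhere.
#' @return data.frame: combo id, k, unit_ids (comma-joined), r2.
#' @export
decode_multi <- function(rates, speed, segment = rep(1L, length(speed)),
                         single_r2 = NULL, min_r2 = 0.1, max_k = 5L,
                         ridge = 1, degree = 3L, n_folds = 10L) {
  rates <- as.matrix(rates)
  ids <- colnames(rates)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(rates)))
  if (is.null(single_r2)) {
    single_r2 <- vapply(seq_len(ncol(rates)), function(j)
      decode_single(rates[, j], speed, segment, degree = degree,
                    n_folds = n_folds)$r2, numeric(1))
    names(single_r2) <- ids
  }
  elig <- ids[!is.na(single_r2[ids]) & single_r2[ids] >= min_r2]
  if (!length(elig)) {
    message("no units with single-unit r2 >= ", min_r2, "; skipping")
    return(data.frame(k = integer(0), unit_ids = character(0),
                      r2 = numeric(0)))
  }
  rows <- list()
  for (k in seq_len(min(max_k, length(elig)))) {
    cmb <- combn(elig, k, simplify = FALSE)
    for (cm in cmb) {
      fr <- cv_decode(rates[, cm, drop = FALSE], speed, segment,
                      degree = degree, n_folds = n_folds, ridge = ridge)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, unit_ids = paste(cm, collapse = ","), r2 = mean(fr))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
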