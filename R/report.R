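# Population summaries, group-level tests, and pipeline orchestration.

#' Population summary of speed-score results
#'
#' Counts and fractions of speed cells overall, by cell type and by sign,
#' with mean +/- SEM of scores and lags and the weak/moderate/strong
#' breakdown.
#'
#' @param scores data.frame from [score_session()] (possibly pooled over
#'   sessions).
#' @return data.frame, one row per group.
#' @export
summarize_population <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  one <- function(d, group) {
    sc <- d$score[d$is_speed_cell]
    lg <- d$lag_s[d$is_speed_cell]
    data.frame(group = group, n_units = nrow(d),
               n_speed_cells = sum(d$is_speed_cell),
               frac_speed_cells = mean(d$is_speed_cell),
               mean_score = if (length(sc)) mean(sc) else NaN,
               sem_score = sem(sc),
               mean_lag_s = if (length(lg)) mean(lg) else NaN,
               sem_lag_s = sem(lg),
               n_weak = sum(d$strength == "weak" & d$is_speed_cell),
               n_moderate = sum(d$strength == "moderate" & d$is_speed_cell),
               n_strong = sum(d$strength == "strong" & d$is_speed_cell))
  }
  groups <- list(one(scores, "all"))
  for (ct in unique(scores$cell_type))
    groups <- c(groups, list(one(scores[scores$cell_type == ct, ],
                                 paste0("cell_type:", ct))))
  for (sg in c("positive", "negative")) {
    d <- scores[scores$sign == sg, ]
    if (nrow(d)) groups <- c(groups, list(one(d, paste0("sign:", sg))))
  }
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out
}

#' Standard group-level comparisons
#'
#' Thin wrapper over base statistical routines: unpaired/paired t-tests,
#' Wilcoxon/Mann-Whitney, with Bonferroni or BH adjustment across the
#' requested comparisons.
#'
#' @param comparisons list of lists with fields `name`, `x`, `y` (optional
#'   for one-sample), `test` (`"t"`, `"wilcoxon"`), `paired` (logical),
#'   `mu` (one-sample null, default 0).
#' @param adjust `"bonferroni"` or `"BH"`.
#' @return data.frame: name, test, direction, statistic, p, p_adj.
#' @export
group_tests <- function(comparisons, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  rows <- lapply(comparisons, function(cmp) {
    test <- if (is.null(cmp$test)) "t" else cmp$test
    paired <- isTRUE(cmp$paired)
    mu <- if (is.null(cmp$mu)) 0 else cmp$mu
    x <- cmp$x; y <- cmp$y
    if ((is.null(y) && length(x) < 2) ||
        (!is.null(y) && (length(x) < 2 || length(y) < 2))) {
      return(data.frame(name = cmp$name, test = test, direction = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        note = "skipped: group with n < 2"))
    }
    # degenerate comparisons (zero-variance differences) are identically
    # equal groups; report p = 1 rather than a test failure
    degen <- if (is.null(y)) stats::sd(x) == 0 && mean(x) == mu
      else if (paired) stats::sd(x - y) == 0 && mean(x - y) == 0
      else FALSE
    if (degen)
      return(data.frame(name = cmp$name, test = test, direction = 0,
                        statistic = 0, p = 1, note = "degenerate: identical"))
    res <- if (test == "t") {
      if (is.null(y)) stats::t.test(x, mu = mu)
      else stats::t.test(x, y, paired = paired)
    } else {
      if (is.null(y)) stats::wilcox.test(x, mu = mu, exact = FALSE)
      else stats::wilcox.test(x, y, paired = paired, exact = FALSE)
    }
    dirn <- if (is.null(y)) sign(mean(x) - mu) else
      if (paired) sign(mean(x - y)) else sign(mean(x) - mean(y))
    data.frame(name = cmp$name, test = test, direction = dirn,
               statistic = unname(res$statistic), p = res$p.value,
               note = "")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = if (adjust == "BH") "BH" else
    "bonferroni")
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on one session
#'
#' Kinematics -> speed scores -> stability and modulation -> bout PSTHs ->
#' decoding -> population summary, with a manifest recording the
#' configuration and seed so reruns are bit-identical. Stage selection via
#' `stages`.
#'
#' @param bundle a [session_bundle()] (e.g. from [generate_session()] or
#'   [read_session()]).
#' @param seed integer seed controlling every stochastic stage.
#' @param n_surr surrogates per unit for scoring (default 10000).
#' @param n_shuffles label shuffles for modulation tests (default 10000).
#' @param n_chance circular-shift repetitions for decoding chance levels.
#' @param stages character subset of
#'   `c("score", "stability", "bouts", "decode")`.
#' @param out_dir optional directory; when given, every result table is
#'   written as CSV via [write_results()].
#' @return named list of result tables plus `manifest`.
#' @export
run_all <- function(bundle, seed = 1L, n_surr = 10000L,
                    n_shuffles = 10000L, n_chance = 100L,
                    stages = c("score", "stability", "bouts", "decode"),
                    out_dir = NULL) {
  results <- list()
  set.seed(seed)
  if ("score" %in% stages) {
    results$scores <- score_session(bundle, n_surr = n_surr)
    results$population <- summarize_population(results$scores)
  }
  if ("stability" %in% stages) {
    trials_b <- tryCatch(assign_blocks(bundle$trials),
                         stability_skipped = function(e) NULL)
    bnd <- bundle
    if (!is.null(trials_b)) bnd$trials <- trials_b
    stab <- list(); mods <- list()
    for (u in bnd$units) {
      stab[[length(stab) + 1L]] <- stability_table(bnd, u)
      for (d in c("cue", "choice", "outcome")) {
        m <- tryCatch(modulation_test(u, bnd$trials, d,
                                      n_shuffles = n_shuffles),
                      test_skipped = function(e) NULL)
        if (!is.null(m)) mods[[length(mods) + 1L]] <- m
      }
    }
    results$stability <- do.call(rbind, stab)
    results$modulation <- do.call(rbind, mods)
  }
  if ("bouts" %in% stages) {
    results$bouts <- bout_psth_session(bundle)
  }
  if ("decode" %in% stages) {
    ds <- decoding_series(bundle)
    single <- lapply(seq_len(ncol(ds$rates)), function(j)
      decode_single(ds$rates[, j], ds$speed, ds$segment))
    r2 <- vapply(single, `[[`, numeric(1), "r2")
    names(r2) <- colnames(ds$rates)
    chance <- vapply(seq_len(ncol(ds$rates)), function(j)
      chance_level(ds$rates[, j, drop = FALSE], ds$speed, ds$segment,
                   n_rep = n_chance), numeric(1))
    results$decoding <- data.frame(unit_id = colnames(ds$rates),
                                   r2 = r2, chance_r2 = chance)
    results$decoding_multi <- decode_multi(ds$rates, ds$speed, ds$segment,
                                           single_r2 = r2)
  }
  results$manifest <- data.frame(
    session_id = bundle$session_id, seed = seed, n_surr = n_surr,
    n_shuffles = n_shuffles, n_chance = n_chance,
    stages = paste(stages, collapse = ","),
    package_version = as.character(utils::packageVersion("speedcells")))
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}
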