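test_that("cross-correlogram matches the brute-force shift-trim oracle", {
  set.seed(101)
  for (rep in 1:5) {
    L <- sample(300:800, 1)
    speed <- as.numeric(stats::filter(rnorm(L), rep(1, 10) / 10,
                                      circular = TRUE))
    rate <- as.numeric(stats::filter(rnorm(L), rep(1, 5) / 5,
                                     circular = TRUE))
    z <- make_zpair(rate, speed)
    ccg <- cross_correlogram(z, max_lag_s = 2, n_min = 5)
    oracle <- bf_ccg(z$rate_z, z$speed_z, 20L)
    expect_equal(ccg$r, oracle, tolerance = 1e-9)
  }
})

test_that("a rate series equal to delayed speed peaks at that delay", {
  set.seed(102)
  base <- as.numeric(stats::filter(rnorm(1200), rep(1, 15) / 15,
                                   circular = TRUE))
  k <- 7L
  speed <- base[1:1000]
  rate <- base[(1:1000) - k + 1200 * ((1:1000) <= k)]  # speed delayed by 7
  z <- make_zpair(rate, speed)
  pk <- speed_score(cross_correlogram(z, max_lag_s = 3, n_min = 5))
  expect_equal(unname(pk["lag_s"]), 0.7)
  expect_gt(pk["score"], 0.95)
  # identity and antisymmetry
  z1 <- make_zpair(speed, speed)
  p1 <- speed_score(cross_correlogram(z1, max_lag_s = 1, n_min = 5))
  expect_equal(unname(p1["score"]), 1, tolerance = 1e-12)
  expect_equal(unname(p1["lag_s"]), 0)
  z2 <- make_zpair(-speed, speed)
  p2 <- speed_score(cross_correlogram(z2, max_lag_s = 1, n_min = 5))
  expect_equal(unname(p2["score"]), -1, tolerance = 1e-12)
})

test_that("the peak is the absolute maximum, with declared tie-breaks", {
  pick <- speedcells:::peak_pick
  expect_equal(unname(pick(c(0.1, 0.46, 0.2), c(-0.1, 0, 0.1))),
               c(0.46, 0))
  expect_equal(unname(pick(c(-0.33, 0.1, 0.2), c(-0.1, 0, 0.1))[1]), -0.33)
  # |r| tie at two lags: closer to zero wins
  expect_equal(unname(pick(c(0.3, 0.1, 0.3), c(-0.2, -0.1, 0.1))[2]), 0.1)
  # exact |lag| tie: more negative lag wins
  expect_equal(unname(pick(c(0.3, 0.1, 0.3), c(-0.1, 0, 0.1))[2]), -0.1)
  expect_equal(unname(pick(c(0.3, 0.1, -0.3), c(-0.1, 0, 0.1))[2]), -0.1)
})

test_that("lagged pairs never cross segment boundaries", {
  set.seed(103)
  rate <- rnorm(400); speed <- rnorm(400)
  z <- make_zpair(rate, speed)
  z$segment <- rep(1:4, each = 100)
  ccg <- cross_correlogram(z, max_lag_s = 2, n_min = 5)
  k <- 15
  # oracle restricted to within-segment pairs
  idx <- (1 + k):400
  ok <- z$segment[idx] == z$segment[idx - k]
  r_by_hand <- stats::cor(z$rate_z[idx][ok], z$speed_z[idx - k][ok])
  expect_equal(ccg$r[which(abs(ccg$lags - k * 0.1) < 1e-9)], r_by_hand,
               tolerance = 1e-9)
  expect_equal(ccg$n_pairs[which(abs(ccg$lags - k * 0.1) < 1e-9)], sum(ok))
})

test_that("surrogates draw 20-50% circular shifts and are reproducible", {
  set.seed(104)
  L <- 1000
  sh <- speedcells:::draw_shifts(500, L)
  expect_true(all(abs(sh) >= 200 & abs(sh) <= 500))
  expect_true(any(sh > 0) && any(sh < 0))

  base <- as.numeric(stats::filter(rnorm(L), rep(1, 10) / 10,
                                   circular = TRUE))
  z <- make_zpair(base + rnorm(L), base)
  set.seed(7); s1 <- surrogate_null(z, n_surr = 200)
  set.seed(7); s2 <- surrogate_null(z, n_surr = 200)
  expect_identical(s1, s2)
  # white-noise pairs: surrogate means center on zero across realizations
  # (within one realization the rotations share the two fixed vectors, so
  # the average is taken over independent pairs)
  set.seed(105)
  mns <- replicate(20, mean(surrogate_null(make_zpair(rnorm(L), rnorm(L)),
                                           n_surr = 100)))
  expect_lt(abs(mean(mns)), 3 * stats::sd(mns) / sqrt(20))
  expect_error(surrogate_null(make_zpair(rnorm(60), rnorm(60))), "short")
})

test_that("the 2-SD rule and empirical p behave as stated", {
  surr <- rnorm(2000, 0, 0.05)
  a <- classify_unit(0.30, 0, surr, unit_id = "a")
  expect_true(a$pass_2sd)
  b <- classify_unit(0.08 + mean(surr), 0, surr, unit_id = "b")
  expect_false(b$pass_2sd)  # 1.6 SD is not enough
  # score equal to every surrogate: p = 1, not significant
  expect_error(classify_unit(0.2, 0, rep(0.2, 2000)), "degenerate")
  d <- classify_unit(mean(surr), 0, surr)
  expect_equal(d$p_emp, 1, tolerance = 0.01)
  expect_false(d$pass_2sd)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  byhand <- sapply(seq_along(p), function(i)
    min(sapply(i:length(p), function(j) min(1, sort(p)[j] * length(p) / j))))
  expect_equal(fdr_adjust(sort(p)), byhand)
})

test_that("strength classes split at |0.2| and |0.4|", {
  expect_identical(strength_class(0.15), "weak")
  expect_identical(strength_class(-0.30), "moderate")
  expect_identical(strength_class(0.45), "strong")
  expect_identical(strength_class(c(-0.19, 0.2, 0.4, -0.41)),
                   c("weak", "moderate", "moderate", "strong"))
})
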