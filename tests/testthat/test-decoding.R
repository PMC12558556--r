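test_that("upper-tail Winsorization caps at the interpolated percentile", {
  x <- 1:100
  w <- winsorize_upper(x)
  expect_equal(max(w), unname(quantile(x, 0.95, type = 7)))
  expect_equal(w[x <= 95], x[x <= 95])           # lower tail untouched
  expect_identical(as.numeric(winsorize_upper(rep(3, 50))), rep(3, 50))
  # idempotent under the fitted cap (the form the CV pipeline uses)
  w2 <- winsorize_upper(as.numeric(w), cap = attr(w, "cap"))
  expect_equal(as.numeric(w2), as.numeric(w))
})

test_that("Gaussian smoothing renormalizes at segment edges", {
  x <- rep(2, 30)
  expect_equal(gauss_smooth(x), x)               # constant fixed point
  seg <- rep(1:2, each = 15)
  y <- c(rep(0, 15), rep(10, 15))
  sm <- gauss_smooth(y, seg)
  expect_equal(sm[1:15], rep(0, 15))             # no bleed across segments
  expect_equal(sm[16:30], rep(10, 15))
})

test_that("contiguous folds partition the series with near-equal sizes", {
  f <- speedcells:::cv_folds(103, 10L)
  expect_equal(length(f), 103)
  expect_true(all(diff(f) >= 0))                 # contiguous, ordered
  expect_lte(diff(range(table(f))), 1)
  expect_error(speedcells:::cv_folds(5, 10L), "too few")
})

test_that("noiseless linear and cubic maps decode nearly perfectly", {
  n <- 400
  rate <- 5 + 3 * sin(seq_len(n) / 15) + 2 * cos(seq_len(n) / 40)
  expect_gte(decode_single(rate, 2 + 3 * rate)$r2, 0.99)
  cubic <- 0.01 * (rate - 5)^3 + 0.5 * rate + 1
  expect_gte(decode_single(rate, cubic)$r2, 0.99)
})

test_that("uninformative rates decode at or below chance", {
  set.seed(71)
  r2s <- replicate(10, decode_single(rnorm(300, 10, 2),
                                     rnorm(300, 15, 5))$r2)
  expect_true(all(r2s <= 0.05))
  expect_lt(median(r2s), 0)
  const <- decode_single(rep(4, 300), rnorm(300, 15, 5))
  expect_true(is.nan(const$r2))
})

test_that("informative synthetic units beat their own chance level", {
  ses <- generate_session(synth_config(duration = 400, n_trials = 24,
    seed = 72, units = list(unit_spec(8, gain = 0.17, cell_type = "FSI"))))
  ds <- decoding_series(ses$bundle)
  r2 <- decode_single(ds$rates[, 1], ds$speed, ds$segment)$r2
  set.seed(72)
  ch <- chance_level(ds$rates[, 1, drop = FALSE], ds$speed, ds$segment,
                     n_rep = 25)
  expect_gt(r2, ch)
  expect_lt(ch, 0.05)
  set.seed(72)
  ch2 <- chance_level(ds$rates[, 1, drop = FALSE], ds$speed, ds$segment,
                      n_rep = 25)
  expect_identical(ch, ch2)                      # seeded determinism
})

test_that("ridge at penalty 1 approximates OLS for a single strong unit", {
  ses <- generate_session(synth_config(duration = 400, n_trials = 24,
    seed = 73, units = list(unit_spec(8, gain = 0.17, cell_type = "FSI"))))
  ds <- decoding_series(ses$bundle)
  ols <- decode_single(ds$rates[, 1], ds$speed, ds$segment)$r2
  mt <- decode_multi(ds$rates, ds$speed, ds$segment, min_r2 = -Inf,
                     max_k = 1)
  expect_lt(abs(mt$r2[1] - ols), 0.05)
})

test_that("perfectly collinear units stay finite under ridge", {
  set.seed(74)
  n <- 200
  rate <- 5 + 3 * sin(seq_len(n) / 10)
  rates <- cbind(a = rate, b = rate)
  speed <- 2 * rate + rnorm(n, 0, 0.5)
  mt <- decode_multi(rates, speed, single_r2 = c(a = 1, b = 1), max_k = 2)
  expect_true(all(is.finite(mt$r2)))
  expect_gt(mt$r2[mt$k == 2], 0.5)
})

test_that("two informative units decode better than one", {
  ses <- generate_session(synth_config(duration = 500, n_trials = 30,
    seed = 75, units = replicate(2, unit_spec(8, gain = 0.17,
                                              cell_type = "FSI"),
                                 simplify = FALSE)))
  ds <- decoding_series(ses$bundle)
  mt <- decode_multi(ds$rates, ds$speed, ds$segment, min_r2 = -Inf,
                     max_k = 2)
  expect_gt(mt$r2[mt$k == 2], mean(mt$r2[mt$k == 1]))
})
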