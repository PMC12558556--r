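test_that("constructed traces yield exactly the enumerated bout events", {
  # 3 s at 0 cm/s then 6 s at 20 cm/s: exactly one onset; with the
  # earliest-candidate rule it lands where the 50%-persistence condition
  # first holds (1 s before the step), and matches the enumeration oracle
  v_step <- c(rep(0, 30), rep(20, 60))
  rs <- make_rs(v_step)
  on <- detect_bouts(rs, "onset")
  expect_equal(nrow(on), 1)
  expect_equal(bf_bouts(v_step, rs$time, "onset"), on$t_ref)
  expect_lte(abs(on$t_ref - 3.0), 1.0)
  expect_equal(nrow(detect_bouts(rs, "offset")), 0)

  # constant 10 cm/s: no events of either kind
  rs_const <- make_rs(rep(10, 120))
  expect_equal(nrow(detect_bouts(rs_const, "onset")), 0)
  expect_equal(nrow(detect_bouts(rs_const, "offset")), 0)

  # 1-s blip above threshold covers only 20% of the post-window: rejected
  v_blip <- c(rep(0, 40), rep(20, 10), rep(0, 60))
  expect_equal(nrow(detect_bouts(make_rs(v_blip), "onset")), 0)
  expect_equal(length(bf_bouts(v_blip, make_rs(v_blip)$time, "onset")), 0)

  # exactly 50% persistence is accepted
  v_half <- c(rep(0, 20), rep(c(20, 0), 25), rep(0, 10))
  expect_equal(nrow(detect_bouts(make_rs(v_half), "onset")),
               length(bf_bouts(v_half, make_rs(v_half)$time, "onset")))
})

test_that("random traces match the exhaustive oracle event-for-event", {
  set.seed(61)
  for (rep in 1:5) {
    v <- pmax(0, as.numeric(stats::filter(rnorm(600, 6, 8), rep(1, 8) / 8,
                                          circular = TRUE)))
    rs <- make_rs(v)
    for (kind in c("onset", "offset")) {
      got <- detect_bouts(rs, kind)
      expect_equal(got$t_ref, bf_bouts(v, rs$time, kind))
    }
  }
})

test_that("a reversed clean step trades its onset for an offset", {
  v_step <- c(rep(0, 40), rep(20, 80))
  expect_equal(nrow(detect_bouts(make_rs(v_step), "onset")), 1)
  expect_equal(nrow(detect_bouts(make_rs(v_step), "offset")), 0)
  expect_equal(nrow(detect_bouts(make_rs(rev(v_step)), "offset")), 1)
  expect_equal(nrow(detect_bouts(make_rs(rev(v_step)), "onset")), 0)
})

test_that("samples exactly at threshold satisfy neither condition", {
  v <- c(rep(5, 30), rep(20, 60))   # pre-window sits exactly at 5 cm/s
  expect_equal(nrow(detect_bouts(make_rs(v), "onset")), 0)
})

test_that("per-event PSTH normalization is exact", {
  set.seed(63)
  ev <- data.frame(kind = "onset", t_ref = c(10, 30, 50))
  u <- spike_train("u", sort(runif(400, 0, 60)), "MSN")
  p <- event_psth(u, ev)
  expect_equal(p$n_events, 3)
  # reconstruct per-event matrices: each retained event has bin-mean 1
  for (tr in ev$t_ref) {
    edges <- tr + seq(-2, 5, by = 0.1)
    cnt <- diff(findInterval(edges - 1e-12, u$spike_times))
    norm <- (cnt / 0.1) / mean(cnt / 0.1)
    expect_lt(abs(mean(norm) - 1), 1e-10)
  }
  expect_lt(abs(mean(p$norm_rate) - 1), 0.2)

  # one event, one spike: its bin is 70, all others 0
  u1 <- spike_train("one", 10.05, "MSN")
  p1 <- event_psth(u1, data.frame(kind = "onset", t_ref = 10))
  expect_equal(max(p1$norm_rate), 70)
  expect_equal(sum(p1$norm_rate > 0), 1)
  expect_lt(abs(mean(p1$norm_rate) - 1), 1e-10)

  # zero-spike events are excluded and counted
  u0 <- spike_train("silent", c(100, 101), "MSN")
  expect_null(event_psth(u0, data.frame(kind = "onset", t_ref = 10)))
  p2 <- event_psth(u0, data.frame(kind = "onset", t_ref = c(10, 99)))
  expect_equal(p2$n_excluded, 1)
  expect_equal(p2$n_events, 1)
})

test_that("a homogeneous Poisson unit has a flat normalized PSTH", {
  set.seed(64)
  u <- spike_train("hom", sort(runif(6000, 0, 600)), "MSN")  # 10 Hz
  ev <- data.frame(kind = "onset", t_ref = seq(10, 580, by = 10))
  p <- event_psth(u, ev)
  expect_true(all(abs(p$norm_rate - 1) <= 3 * p$sem + 1e-9))
})

test_that("session-level bout PSTHs track the speed trace direction", {
  ses <- generate_session(synth_config(duration = 500, n_trials = 25,
    seed = 65, units = list(unit_spec(5, gain = 0.17, cell_type = "MSN"))))
  tab <- bout_psth_session(ses$bundle)
  on <- tab[tab$kind == "onset", ]
  expect_gt(nrow(on), 0)
  expect_gt(mean(on$norm_rate[on$bin_center > 0]),
            mean(on$norm_rate[on$bin_center < 0]))
  expect_gt(mean(on$speed_mean[on$bin_center > 0]),
            mean(on$speed_mean[on$bin_center < 0]))
})
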