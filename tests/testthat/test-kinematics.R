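test_that("5-point smoothing is exact on constants, ramps and impulses", {
  n <- 10
  tt <- (0:(n - 1)) * 0.1
  const <- position_track(tt, rep(2, n), rep(3, n), dt = 0.1)
  expect_equal(smooth_positions(const)$x, rep(2, n))

  expect_error(position_track((0:3) * 0.1, 0:3, rep(0, 4), dt = 0.1))
  sm <- speedcells:::boxcar_truncated(0:4, 5L)
  expect_equal(sm[3], 2)            # ramp center is a fixed point

  imp <- speedcells:::boxcar_truncated(c(0, 0, 5, 0, 0), 5L)
  expect_equal(imp[3], 1.0)         # 5-point mean of a unit-area impulse
})

test_that("speed is displacement over dt with midpoint timestamps", {
  n <- 20
  still <- position_track((0:(n - 1)) * 0.1, rep(1, n), rep(1, n), dt = 0.1)
  expect_equal(compute_speed(still)$speed, rep(0, n - 1))

  # 3-4-5 triangle: 0.3 cm in x and 0.4 cm in y per 0.1 s -> 5 cm/s
  tri <- position_track((0:9) * 0.1, (0:9) * 0.3, (0:9) * 0.4, dt = 0.1)
  sp <- compute_speed(tri)
  expect_equal(sp$speed, rep(5, 9))
  expect_equal(sp$timestamps[1], 0.05)
  expect_equal(length(sp$speed), 9)

  # the tracking system's native dt: 0.256 cm per 0.0256 s -> 10 cm/s
  tk <- position_track((0:9) * 0.0256, (0:9) * 0.256, rep(0, 10),
                       dt = 0.0256)
  expect_equal(compute_speed(tk)$speed, rep(10, 9))
})

test_that("masking removes zero speed, >60 cm/s, and out-of-task samples", {
  tr <- line_track(n = 201, dt = 0.1, vx = 20)   # 20 cm/s for 20 s
  sp <- compute_speed(tr)
  sp$speed[10] <- 75     # mistracking spike inside a trial
  sp$speed[11] <- 0      # frozen-position sample inside a trial
  trials <- trial_table(data.frame(trial_id = 1:2, t_start = c(0, 12),
                                   t_end = c(8, 20), cue = "visual",
                                   choice = "left", outcome = "rewarded"))
  m <- mask_epochs(sp, trials, max_speed = 60)
  expect_false(m$valid[10])
  expect_false(m$valid[11])
  between <- m$timestamps > 8 & m$timestamps < 12
  expect_false(any(m$valid[between]))
  expect_true(m$valid[5])
  expect_error(mask_epochs(sp, trials[0, ]), "empty")
})

test_that("overlapping windows follow the stride arithmetic", {
  tr <- line_track(n = 101, dt = 0.1, vx = 10)   # exactly 10 s of speed
  sp <- compute_speed(tr)
  trials <- trial_table(data.frame(trial_id = 1, t_start = 0, t_end = 10.1,
                                   cue = "visual", choice = "left",
                                   outcome = "rewarded"))
  sp <- mask_epochs(sp, trials)
  u <- spike_train("u1", c(2.1, 2.2, 2.5, 2.8, 2.95), "MSN")
  b <- bin_pair(sp, u, bin_s = 1.0, overlap_s = 0.9)
  expect_equal(length(b$bin_centers), 91)  # floor((10-1)/0.1)+1
  # all 5 spikes sit inside the window starting at 2.0 s
  w <- which(abs(b$bin_centers - 2.5) < 1e-9)
  expect_equal(b$rate_binned[w], 5)
  # disjoint bins conserve the in-mask spike count exactly
  b0 <- bin_pair(sp, u, bin_s = 1.0, overlap_s = 0)
  expect_equal(sum(b0$rate_binned * b0$bin_s), 5)
})

test_that("z-scoring uses the population SD and is idempotent", {
  tr <- line_track(n = 200, dt = 0.1)
  sp <- compute_speed(tr)
  sp$speed <- sp$speed + sin(seq_along(sp$speed))  # give speed variance
  trials <- trial_table(data.frame(trial_id = 1, t_start = 0, t_end = 19,
                                   cue = "visual", choice = "left",
                                   outcome = "rewarded"))
  sp <- mask_epochs(sp, trials)
  u <- spike_train("u1", seq(0.05, 18, by = 0.31), "MSN")
  z <- zscore_pair(bin_pair(sp, u))
  expect_lt(abs(mean(z$rate_z)), 1e-10)
  expect_lt(abs(sqrt(mean(z$rate_z^2)) - 1), 1e-10)
  expect_lt(abs(sqrt(mean(z$speed_z^2)) - 1), 1e-10)
  # hand example: population-SD z-scores of [1,2,3]
  zs <- (c(1, 2, 3) - 2) / sqrt(2 / 3)
  expect_equal(round(zs, 4), c(-1.2247, 0, 1.2247))
  # silent unit -> degenerate signal
  silent <- spike_train("u0", numeric(0), "MSN")
  expect_error(zscore_pair(bin_pair(sp, silent)), "degenerate")
})

test_that("unit inclusion is strictly above the 0.5 Hz in-task rate", {
  trials <- trial_table(data.frame(trial_id = 1, t_start = 0, t_end = 100,
                                   cue = "visual", choice = "left",
                                   outcome = "rewarded"))
  mk <- function(rate) spike_train(paste0("r", rate),
                                   seq(0, 99.99, length.out = rate * 100),
                                   "MSN")
  units <- list(mk(0.4), mk(0.6), spike_train("exact",
                seq(0, 99.99, length.out = 50), "MSN"))
  fl <- filter_units(units, trials, min_rate = 0.5)
  kept <- vapply(fl$included, `[[`, character(1), "unit_id")
  expect_identical(kept, "r0.6")
  expect_true(all(c("r0.4", "exact") %in% fl$excluded$unit_id))
})

test_that("tightening the speed cap never adds valid windows", {
  ses <- tiny_session(seed = 11)
  sp60 <- mask_epochs(compute_speed(smooth_positions(ses$bundle$position)),
                      ses$bundle$trials, max_speed = 60)
  sp30 <- mask_epochs(compute_speed(smooth_positions(ses$bundle$position)),
                      ses$bundle$trials, max_speed = 30)
  u <- ses$bundle$units[[1]]
  expect_lte(length(bin_pair(sp30, u)$bin_centers),
             length(bin_pair(sp60, u)$bin_centers))
})

test_that("generator truth and kinematics-recomputed speed agree closely", {
  cfg <- synth_config(duration = 300, n_trials = 20, seed = 9,
                      artifact_rate = 0)
  set.seed(9)
  prof <- generate_speed_profile(cfg)
  sp <- compute_speed(smooth_positions(prof$track))
  rmse <- sqrt(mean((sp$speed - prof$true_speed)^2))
  expect_lt(rmse, 0.05 * mean(prof$true_speed))
})
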