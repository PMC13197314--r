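grid <- build_condition_grid()

test_that("finite-difference speed matches hand-computed differences", {
  expect_equal(finite_diff_speed(c(0, 0.004, 0.008), 250), c(1, 1))
  xyz <- rbind(c(0, 0, 0), c(0.003, 0.004, 0), c(0.006, 0.008, 0))
  expect_equal(finite_diff_speed(xyz, 250), c(1.25, 1.25))
  expect_equal(finite_diff_speed(rep(0.5, 10), 250), rep(0, 9))
  expect_error(finite_diff_speed(1, 250), "2 samples")
})

test_that("cube motion onset and the pre-motion minimum are located", {
  ev <- detect_cube_motion(c(0, 0.01, 0.05, 0.5))
  expect_equal(ev$onset, 3L) # first sample strictly above 0.04 m/s
  expect_error(detect_cube_motion(rep(0, 10)), "never")
  # monotone ramp: minimum sits at the last pre-threshold sample
  ramp <- seq(0, 0.5, length.out = 26) # crosses 0.04 at sample 4
  ev <- detect_cube_motion(ramp)
  expect_equal(ev$onset, 4L)
  expect_equal(ev$i_min_cs, 2L) # search starts at index 2 by default
  ev <- detect_cube_motion(ramp, from = 3L)
  expect_equal(ev$i_min_cs, 3L)
})

test_that("contact detection returns the sample before the 0.4 crossing", {
  # build a speed series whose acceleration over the window is
  # (0, -1, -5, -10, -2): normalized (0, 0.1, 0.5, 1, 0.2), first > 0.4 at
  # the third window sample, so contact is the second
  rate <- 250
  accel <- c(0, -1, -5, -10, -2)
  speed <- c(1.0, 2 + cumsum(c(0, accel)) / rate) # lead-in outside window
  win <- 3:7 # window samples whose acceleration is `accel`
  got <- detect_contact(speed, i_max_fs = win[1], i_min_cs = win[5],
                        config = kinematic_config(sampling_rate = rate))
  expect_equal(got, win[3] - 1L)

  # single-sample spike normalizes to 1 and triggers immediately
  speed2 <- c(1, 2, 2, 2, 1.5, 1.5, 1.5)
  got2 <- detect_contact(speed2, 2L, 6L,
                         kinematic_config(sampling_rate = rate))
  expect_equal(got2, 5L - 1L)

  # values exactly at 0.4 do not trigger (strict inequality)
  accel3 <- c(-4, -4, -10, -4)
  speed3 <- c(3, 3, 3 + cumsum(accel3) / rate)
  got3 <- detect_contact(speed3, 2L, 6L,
                         kinematic_config(sampling_rate = rate))
  expect_equal(got3, 5L - 1L) # only the minimum (sample 5) crosses

  expect_error(detect_contact(c(1, 2, 3, 4), 4L, 2L), "empty")
  expect_error(detect_contact(c(1, 2, 3, 4), 2L, 4L), "no fingertip deceleration")
})

test_that("noise-free extraction recovers the generator's ground truth", {
  for (arch in c("inverse_duration_amplitude", "temporal_invariance",
                 "late_impulse")) {
    p <- noise_free_profile(arch)
    for (ci in c(1, 6, 12)) {
      out <- synthesize_trial(p, grid[ci, ])
      rec <- extract_trial(out$trajectory, grid[ci, ])
      gt <- out$record
      expect_equal(rec$A_mm, gt$A_mm, tolerance = 0.02)
      expect_lte(abs(rec$D_s - gt$D_s), 2 / 250)
      expect_equal(rec$IS_mps, gt$IS_mps, tolerance = 0.02)
      expect_equal(rec$spatial_error_pct, gt$spatial_error_pct,
                   tolerance = 0.5)
      ev <- attr(rec, "events")
      expect_true(ev$t_onset < ev$t_maxFS)
      expect_true(ev$t_maxFS <= ev$t_contact + 1 / 250)
      expect_true(ev$t_contact + 1 / 250 <= ev$t_minCS)
      expect_true(ev$t_minCS <= ev$t_cube_stop)
    }
  }
})

test_that("strike onset lands at the generator's strike start", {
  p <- noise_free_profile("inverse_duration_amplitude")
  out <- synthesize_trial(p, grid[6, ])
  rec <- extract_trial(out$trajectory, grid[6, ])
  ev <- attr(rec, "events")
  # construction: 25 rest + 100 arming + 12 hold samples precede the strike
  t_strike_start <- (25 + 100 + 12 - 1) / 250
  expect_lte(abs(ev$t_onset - t_strike_start), 2 / 250)
})

test_that("onset detection handles degenerate inputs", {
  still <- structure(list(sampling_rate = 250, time = (0:99) / 250,
                          fingertip_xyz = cbind(x = rep(0, 100), y = 0, z = 0),
                          cube_axis_position = rep(0, 100)),
                     class = "strike_trajectory")
  fs <- c(NA, finite_diff_speed(still$fingertip_xyz, 250))
  expect_error(detect_strike_onset(fs, fs, 50L), "never moves")
  # zero fraction degenerates to the reversal sample itself
  p <- noise_free_profile("temporal_invariance")
  out <- synthesize_trial(p, grid[3, ])
  xyz <- out$trajectory$fingertip_xyz
  fs <- c(NA, finite_diff_speed(xyz, 250))
  vx <- c(NA, diff(xyz[, 1]) * 250)
  i_c <- which(xyz[, 1] == 0 & seq_len(nrow(xyz)) > 150)[1]
  cfg0 <- kinematic_config(onset_speed_fraction = 1e-9)
  cfg5 <- kinematic_config(onset_speed_fraction = 0.05)
  expect_equal(detect_strike_onset(vx, fs, i_c, cfg0),
               detect_strike_onset(vx, fs, i_c, cfg5))
})

test_that("extraction is deterministic and excludes undetectable trials", {
  coh <- small_cohort()
  cond <- grid[grid$demand_rank == coh$trials$demand_rank[1], ]
  tr <- coh$trajectories[[coh$trials$trial_id[1]]]
  r1 <- extract_trial(tr, cond)
  r2 <- extract_trial(tr, cond)
  expect_identical(r1, r2)

  # a trial whose cube never moves is excluded with a reason code
  broken <- coh
  broken$trajectories[[1]]$cube_axis_position[] <- 0
  sub <- broken
  keep <- broken$trials$trial_id[1:5]
  sub$trials <- broken$trials[broken$trials$trial_id %in% keep, ]
  sub$trajectories <- broken$trajectories[keep]
  ex <- extract_cohort(sub)
  expect_equal(nrow(ex$exclusions), 1L)
  expect_equal(ex$exclusions$reason, "cube_never_moved")
  expect_equal(nrow(ex$trials), 4L)
})

test_that("extraction on the whole cohort reproduces ground truth within tolerance", {
  coh <- small_cohort()
  ex <- extract_cohort(coh)
  expect_equal(nrow(ex$exclusions), 0L)
  m <- merge(ex$trials, coh$trials[, c("trial_id", "A_mm", "D_s", "IS_mps")],
             by = "trial_id", suffixes = c("", ".gt"))
  expect_lte(max(abs(m$A_mm / m$A_mm.gt - 1)), 0.02)
  expect_lte(max(abs(m$D_s - m$D_s.gt)), 2 / 250)
  expect_lte(max(abs(m$IS_mps / m$IS_mps.gt - 1)), 0.02)
})

test_that("low-pass filtering before extraction would distort the collision", {
  # the contact rule relies on the raw ~16 ms collision transient; a 10 Hz
  # moving-average filter (25 samples at 250 Hz) must visibly corrupt the
  # recovered impact speed, which is why no smoothing is ever applied
  p <- noise_free_profile("inverse_duration_amplitude")
  out <- synthesize_trial(p, grid[6, ])
  traj <- out$trajectory
  k <- 25
  sm <- stats::filter(traj$fingertip_xyz[, 1], rep(1 / k, k), sides = 2)
  pad <- (k - 1) / 2
  n <- length(sm)
  sm[seq_len(pad)] <- traj$fingertip_xyz[seq_len(pad), 1]
  sm[(n - pad + 1):n] <- traj$fingertip_xyz[(n - pad + 1):n, 1]
  traj$fingertip_xyz[, 1] <- as.numeric(sm)
  rec <- tryCatch(extract_trial(traj, grid[6, ]),
                  strikekin_kin_error = function(e) e)
  distorted <- inherits(rec, "strikekin_kin_error") ||
    abs(rec$IS_mps / out$record$IS_mps - 1) > 0.05
  expect_true(distorted)
})
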