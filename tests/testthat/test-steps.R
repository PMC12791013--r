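test_that("ankle speed is zero when static and ~v at constant velocity", {
  fps <- 60
  traj <- matrix(3, 100, 3)
  expect_true(all(ankle_speed(traj, fps) == 0))
  traj2 <- cbind(seq(0, 99) * 2 / fps, 0, 0)   # 2 units/s along x
  sp <- ankle_speed(traj2, fps)
  expect_equal(sp[10:90], rep(2, 81), tolerance = 1e-9)
  # smoothing window spans 0.1 s: 6 frames at 60 fps
  x <- numeric(50); x[25] <- 1
  sm <- skelimpute:::smooth_series(x, round(0.1 * 60))
  expect_equal(sum(sm > 0), 6)
  expect_error(ankle_speed(matrix(c(1, NA), 2, 1), fps), "contiguous")
})

test_that("the detector finds constructed bumps near their analytic anchors", {
  tr <- make_step_trace(5, step_height = 30, step_duration = 0.8, seed = 11)
  sp <- ankle_speed(tr$position, tr$fps)
  st <- detect_steps(sp, fps = tr$fps)
  expect_equal(nrow(st), 5)
  expect_true(all(abs(st$t_start - tr$truth$start) <= 2))
  expect_true(all(abs(st$t_stop - tr$truth$stop) <= 2))
  expect_true(all(st$swing_duration >= 0.6))
})

test_that("flat speed and sub-gate bumps yield no steps", {
  expect_equal(nrow(detect_steps(rep(0.5, 300), fps = 60)), 0)
  low <- make_step_trace(4, step_height = 15, seed = 12)   # below height 20
  expect_equal(nrow(detect_steps(ankle_speed(low$position, 60), fps = 60)), 0)
  short <- make_step_trace(4, step_duration = 0.3, seed = 13)  # interval < 0.6 s
  expect_equal(nrow(detect_steps(ankle_speed(short$position, 60), fps = 60)), 0)
  narrow <- make_step_trace(4, step_duration = 0.05, rise_time = 0.04,
                            seed = 14)                     # width < 0.16 s
  expect_equal(nrow(detect_steps(ankle_speed(narrow$position, 60), fps = 60)), 0)
})

test_that("every emitted step satisfies all gates post hoc", {
  tr <- make_step_trace(8, step_height = c(30, 50), step_duration = c(0.8, 1.2),
                        seed = 15)
  sp <- ankle_speed(tr$position, tr$fps)
  st <- detect_steps(sp, fps = tr$fps)
  expect_gt(nrow(st), 0)
  expect_true(all(st$height >= 20))
  expect_true(all(st$prominence >= 21))
  expect_true(all(st$swing_duration >= 0.6))
  expect_true(all(st$t_start < st$t_peak & st$t_peak < st$t_stop))
})

test_that("detection is invariant to translating the trajectory", {
  tr <- make_step_trace(4, seed = 16)
  a <- detect_steps(ankle_speed(tr$position, 60), fps = 60)
  b <- detect_steps(ankle_speed(tr$position + 1234.5, 60), fps = 60)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the position gate discards swings without lift-off", {
  tr <- make_step_trace(3, seed = 17)
  sp <- ankle_speed(tr$position, 60)
  flat_height <- rep(0, length(sp))
  st_flat <- detect_steps(sp, fps = 60, height = flat_height)
  expect_equal(nrow(st_flat), 0)   # never lower at start/stop than interior
  lifted <- numeric(length(sp))
  for (i in seq_len(nrow(tr$truth))) {
    idx <- tr$truth$start[i]:tr$truth$stop[i]
    lifted[idx] <- sin(seq(0, pi, length.out = length(idx))) * 5
  }
  st_lift <- detect_steps(sp, fps = 60, height = lifted)
  expect_equal(nrow(st_lift), nrow(tr$truth))
})

test_that("step features: straight swings, time conversion, path inequality", {
  fps <- 60
  traj <- cbind(seq(0, 10, length.out = 49), 0, 0)  # 10 units over 48 frames
  step <- list(t_start = 1, t_stop = 49)
  f <- step_features(step, traj, fps)
  expect_equal(f$stride_length, 10, tolerance = 1e-9)
  expect_equal(f$swing_duration, 0.8)               # 48 frames at 60 fps
  zig <- traj
  zig[, 2] <- rep(c(0, 0.5), length.out = 49)
  expect_gt(step_features(step, zig, fps)$stride_length, 10)
  traj[5, ] <- NA
  expect_error(step_features(step, traj, fps), "missing")
})

test_that("the before/after harness recovers gap-hidden steps exactly", {
  tr <- make_step_trace(10, step_height = 30, step_duration = 0.8, seed = 18)
  Tn <- length(tr$position)
  co <- array(0, c(Tn, 2, 2))
  co[, 1, 1] <- tr$position           # "ankle" x; flat y (2D: no height gate)
  co[, 2, 1] <- 50                    # a second, static keypoint
  full <- skel_recording(co, 60, c("ankle", "hip"))
  # hide steps 3..5 behind a native gap
  g0 <- tr$truth$start[3] - round(0.5 * 60)
  g1 <- tr$truth$stop[5] + round(0.5 * 60)
  co2 <- co
  co2[g0:g1, 1, ] <- NaN
  gappy <- skel_recording(co2, 60, c("ankle", "hip"))
  perfect <- structure(list(recording = full,
                            still_missing = matrix(FALSE, Tn, 2),
                            per_window_error = data.frame(), method = "oracle"),
                       class = "skel_imputed")
  res <- count_steps_before_after(gappy, perfect, ankles = "ankle")
  expect_equal(res$n_before, 7)
  expect_equal(res$n_after, 10)
  expect_equal(res$n_after - res$n_before, 3)
  expect_true(all(res$steps_after$side == "ankle"))
  # identity case: no gaps anywhere
  none <- count_steps_before_after(full, perfect, ankles = "ankle")
  expect_equal(none$n_before, none$n_after)
})
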