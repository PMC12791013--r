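test_that("linear interpolation is exact on linear gaps and respects edges", {
  co <- array(0, c(11, 2, 2))
  co[, 1, 1] <- 0:10; co[, 1, 2] <- 5 - (0:10)
  co[, 2, 1] <- 2 * (0:10); co[, 2, 2] <- 7
  full <- co
  co[2:10, 1, ] <- NaN
  rec <- skel_recording(co, 60)
  li <- linear_interpolate(rec)
  expect_false(any(li$still_missing))
  expect_arrays_equal(li$recording$coords, full, 1e-12)
  expect_equal(li$recording$coords[5, 1, 1], 4)   # value t at frame t
  # leading-edge gap has no left anchor: left missing
  co2 <- full
  co2[1:3, 2, ] <- NaN
  li2 <- linear_interpolate(skel_recording(co2, 60))
  expect_true(all(li2$still_missing[1:3, 2]))
  expect_false(any(li2$still_missing[, 1]))
  # observed cells bit-identical
  expect_identical(li2$recording$coords[4:11, 2, ], co2[4:11, 2, ])
})

test_that("estimated error is the mean std over masked cells", {
  s <- preprocess_sample(rand_sample(L = 10, K = 2, D = 2, seed = 1))
  gm <- matrix(FALSE, 10, 2); gm[2:6, 1] <- TRUE; gm[3:7, 2] <- TRUE
  std <- array(0.5, c(10, 2, 2))
  pr <- structure(list(mean = s$coords, std = std, gap_mask = gm),
                  class = "skel_prediction")
  expect_equal(estimated_error(pr), 0.5)
  std2 <- std
  std2[, 1, ] <- 0.1; std2[, 2, ] <- 0.3   # 5 masked cells each
  pr$std <- std2
  expect_equal(estimated_error(pr), 0.2)
  pr$std <- NULL
  expect_error(estimated_error(pr), "probabilistic")
})

test_that("filter_by_error implements the threshold contract", {
  err <- c(0, 0.05, 0.2, 1)
  expect_equal(filter_by_error(err, Inf), rep(TRUE, 4))
  expect_equal(filter_by_error(err, 0), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(filter_by_error(err, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  res <- lapply(err, function(e) list(error = e))
  expect_length(filter_by_error(res, 0.1), 2)
})

test_that("imputing a complete recording is the identity", {
  m <- build_model("gru", K = 4, D = 3, L = 20, hidden = 8, n_layers = 1, seed = 1)
  rec <- rand_recording(T = 100, K = 4, D = 3, seed = 2)
  out <- impute_recording(m, rec)
  expect_identical(out$recording$coords, rec$coords)
  expect_false(any(out$still_missing))
  expect_equal(nrow(out$per_window_error), 0)
})

test_that("imputation fills bounded gaps, leaves hopeless ones, never touches observations", {
  m <- build_model("gru", K = 4, D = 3, L = 20, hidden = 8, n_layers = 1, seed = 1)
  m$n_missing_trained <- 2
  rec <- rand_recording(T = 200, K = 4, D = 3, seed = 3)
  co <- rec$coords
  co[50:54, 2, ] <- NaN            # short interior gap: imputable
  co[100:118, 3, ] <- NaN          # 19 frames > L - 2 = 18: prohibitively long
  co[1:4, 4, ] <- NaN              # leading edge: no left anchor
  rec <- skel_recording(co, 60, rec$keypoint_names)
  out <- impute_recording(m, rec, error_threshold = Inf)
  expect_false(any(out$still_missing[50:54, 2]))
  expect_true(all(out$still_missing[100:118, 3]))
  expect_true(all(out$still_missing[1:4, 4]))
  expect_true(all(is.finite(out$recording$coords[50:54, 2, ])))
  obs <- !rec$missing
  for (d in 1:3) {
    a <- out$recording$coords[, , d][obs]
    b <- rec$coords[, , d][obs]
    expect_identical(a, b)
  }
  expect_setequal(out$per_window_error$reason[!out$per_window_error$accepted],
                  c("gap_too_long", "gap_at_edge"))
})

test_that("windows exceeding the trained simultaneous-missing regime are skipped", {
  m <- build_model("gru", K = 4, D = 3, L = 20, hidden = 8, n_layers = 1, seed = 1)
  m$n_missing_trained <- 1
  rec <- rand_recording(T = 100, K = 4, D = 3, seed = 4)
  co <- rec$coords
  co[40:44, 1, ] <- NaN
  co[42:46, 2, ] <- NaN            # overlapping -> 2 simultaneous
  rec <- skel_recording(co, 60, rec$keypoint_names)
  out <- impute_recording(m, rec, error_threshold = Inf)
  expect_true(any(out$per_window_error$reason == "too_many_simultaneous"))
  expect_true(all(out$still_missing[42:44, 1:2]))
  out2 <- impute_recording(m, rec, error_threshold = Inf, max_simultaneous = 2)
  expect_false(any(out2$still_missing))
})

test_that("the error threshold gates window acceptance", {
  m <- build_model("gru", K = 4, D = 3, L = 20, hidden = 8, n_layers = 1,
                   proba = TRUE, seed = 1)
  rec <- rand_recording(T = 100, K = 4, D = 3, seed = 5)
  co <- rec$coords
  co[30:33, 1, ] <- NaN
  co[70:73, 2, ] <- NaN
  rec <- skel_recording(co, 60, rec$keypoint_names)
  all_in <- impute_recording(m, rec, error_threshold = Inf)
  expect_false(any(all_in$still_missing))
  expect_true(all(is.finite(all_in$per_window_error$estimated_error)))
  none <- impute_recording(m, rec, error_threshold = 0)
  expect_true(all(none$still_missing == rec$missing))
  expect_true(all(none$per_window_error$reason == "error_above_threshold"))
})
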