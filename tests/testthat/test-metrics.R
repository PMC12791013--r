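brute_metrics <- function(pred, gt, mask) {
  # independent explicit-loop oracle for rmse/mpjpe/pck distances
  ds <- c()
  for (t in seq_len(nrow(mask))) for (k in seq_len(ncol(mask))) {
    if (mask[t, k]) {
      sq <- 0
      for (d in seq_len(dim(pred)[3])) sq <- sq + (pred[t, k, d] - gt[t, k, d])^2
      ds <- c(ds, sqrt(sq))
    }
  }
  ds
}

test_that("rmse/mpjpe/pck reproduce hand-computed cases", {
  gt <- array(0, c(3, 2, 3))
  pred <- gt
  gm <- matrix(FALSE, 3, 2)
  gm[1, 1] <- TRUE
  expect_equal(rmse(pred, gt, gm), 0)
  expect_equal(mpjpe(pred, gt, gm), 0)
  expect_equal(pck(pred, gt, gm, 0.01, max_dist = 1), 1.0)
  pred[1, 1, ] <- c(3, 4, 0)              # 3-4-5 triangle
  expect_equal(rmse(pred, gt, gm), 5.0)
  expect_equal(mpjpe(pred, gt, gm), 5.0)
  gm[2, 2] <- TRUE                        # second point exact
  expect_equal(rmse(pred, gt, gm), sqrt(25 / 2))
  expect_equal(mpjpe(pred, gt, gm), 2.5)
  # pck cases: errors {0, 5}, thresholds
  expect_equal(pck(pred, gt, gm, th = 0.5, max_dist = 2), 0.5)  # 1.0 cutoff
  expect_equal(pck(pred, gt, gm, th = 0.01, max_dist = 1), 0.5)
  pred[2, 2, ] <- c(10, 0, 0)
  expect_equal(pck(pred, gt, gm, th = 0.1, max_dist = 10), 0.0)
  expect_error(rmse(pred, gt, matrix(FALSE, 3, 2)), "undefined")
})

test_that("2D metrics drop the z term by construction", {
  gt <- array(0, c(2, 2, 2))
  pred <- gt; pred[1, 1, ] <- c(3, 4)
  gm <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(rmse(pred, gt, gm), 5)
})

test_that("mpjpe <= rmse with equality iff all distances are equal", {
  for (seed in 1:10) {
    set.seed(seed)
    pred <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
    gt <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
    gm <- matrix(runif(15) < 0.5, 5, 3); gm[1, 1] <- TRUE
    expect_lte(mpjpe(pred, gt, gm), rmse(pred, gt, gm) + 1e-12)
  }
  gt <- array(0, c(2, 2, 3)); pred <- gt
  pred[1, 1, 1] <- 2; pred[2, 2, 2] <- 2
  gm <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(mpjpe(pred, gt, gm), rmse(pred, gt, gm))
})

test_that("pck is monotone non-decreasing in the threshold", {
  set.seed(2)
  pred <- array(rnorm(60), c(5, 2, 2)); gt <- array(rnorm(60), c(5, 2, 2))
  gm <- matrix(TRUE, 5, 2)
  ths <- seq(0.01, 1, by = 0.05)
  vals <- sapply(ths, function(th) pck(pred, gt, gm, th, max_dist = 3))
  expect_true(all(diff(vals) >= 0))
})

test_that("metrics ignore errors on unmasked cells", {
  set.seed(3)
  gt <- array(rnorm(36), c(3, 4, 3))
  pred <- gt + 0.1
  gm <- matrix(FALSE, 3, 4); gm[2, c(1, 3)] <- TRUE
  base <- c(rmse(pred, gt, gm), mpjpe(pred, gt, gm), pck(pred, gt, gm, 0.5, 1))
  pred[1, 2, ] <- 1e6
  after <- c(rmse(pred, gt, gm), mpjpe(pred, gt, gm), pck(pred, gt, gm, 0.5, 1))
  expect_identical(base, after)
})

test_that("max inter-keypoint distance: unit square, missing exclusion, oracle", {
  co <- array(0, c(1, 4, 2))
  co[1, , ] <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(max_interkeypoint_distance(skel_recording(co, 60)), sqrt(2))
  co2 <- co
  co2[1, 3, ] <- NaN   # drop one diagonal corner
  expect_equal(max_interkeypoint_distance(skel_recording(co2, 60)), sqrt(2))
  co2[1, 4, ] <- NaN   # drop both corners of one side: max is now an edge
  expect_equal(max_interkeypoint_distance(skel_recording(co2, 60)), 1)
  # brute force O(T K^2) oracle on random data
  rec <- rand_recording(T = 30, K = 5, D = 3, seed = 4)
  best <- 0
  for (t in 1:30) for (i in 1:4) for (j in (i + 1):5) {
    best <- max(best, sqrt(sum((rec$coords[t, i, ] - rec$coords[t, j, ])^2)))
  }
  expect_equal(max_interkeypoint_distance(rec), best)
})

test_that("movement matches hand cases and a brute-force mean", {
  co <- array(1, c(5, 2, 3))
  expect_equal(movement(co), 0)
  for (d in 1:3) co[, , d] <- matrix(0.3 * (0:4), 5, 2)
  expect_equal(movement(co), 0.3)
  set.seed(5)
  co <- array(rnorm(5 * 2 * 3), c(5, 2, 3))
  acc <- 0; n <- 0
  for (t in 2:5) for (k in 1:2) for (d in 1:3) {
    acc <- acc + abs(co[t, k, d] - co[t - 1, k, d]); n <- n + 1
  }
  expect_equal(movement(co), acc / n, tolerance = 1e-12)
  co[1, 1, 1] <- NaN
  expect_error(movement(co), "missing")
})

test_that("periodicity finds the dominant spectral line, scales linearly", {
  L <- 64
  co <- array(0, c(L, 2, 2))
  co[, 1, 1] <- 3 * sin(2 * pi * 4 * (0:(L - 1)) / L)  # exact bin: amplitude 3
  expect_equal(periodicity(co), 3, tolerance = 1e-9)
  expect_equal(periodicity(co * 2), 6, tolerance = 1e-9)
  # direct spectrum computation oracle
  sp <- 2 * Mod(stats::fft(co[, 1, 1]))[2:(L / 2 + 1)] / L
  expect_equal(periodicity(co), max(sp))
  expect_equal(periodicity(array(5, c(16, 2, 2))), 0)   # DC excluded
})
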