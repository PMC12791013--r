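# independent run-length-encoding oracle for missingness statistics
mask_to_rec <- function(mask, seed = 1) {
  Tn <- nrow(mask); K <- ncol(mask)
  co <- array(rnorm(Tn * K * 2), c(Tn, K, 2))
  for (d in 1:2) { p <- co[, , d]; p[mask] <- NaN; co[, , d] <- p }
  skel_recording(co, 60)
}

test_that("estimate_gap_stats matches a run-length-encoding oracle on random masks", {
  for (seed in 1:5) {
    mask <- with_seed(seed, matrix(runif(400) < 0.15, 100, 4))
    rec <- mask_to_rec(mask)
    st <- estimate_gap_stats(rec)
    ev <- rle_oracle(mask)
    if (is.null(ev)) next
    counts <- tabulate(ev[, "k"], 4)
    expect_equal(unname(st$p_keypoint), counts / sum(counts))
    for (k in which(counts > 0)) {
      tb <- table(ev[ev[, "k"] == k, "len"])
      expect_equal(st$gap_length_pmf[[k]],
                   stats::setNames(as.numeric(tb) / sum(tb), names(tb)))
    }
  }
})

test_that("single-keypoint fixed-length gaps give one-hot statistics", {
  mask <- matrix(FALSE, 60, 3)
  mask[c(10:14, 30:34, 50:54), 2] <- TRUE
  st <- estimate_gap_stats(mask_to_rec(mask))
  expect_equal(unname(st$p_keypoint), c(0, 1, 0))
  expect_equal(st$gap_length_pmf[[2]], c("5" = 1))
  # inter-gap spacings: 15 observed frames between consecutive gaps
  expect_equal(st$intergap_pmf, c("15" = 1))
})

test_that("no missing data falls back to uniform distributions", {
  rec <- rand_recording(T = 50, K = 4, seed = 1)
  st <- estimate_gap_stats(rec)
  expect_equal(unname(st$p_keypoint), rep(0.25, 4))
  expect_equal(sum(st$gap_length_pmf[[1]]), 1, tolerance = 1e-9)
  expect_true(all(st$gap_length_pmf[[1]] == st$gap_length_pmf[[1]][1]))
  st2 <- estimate_gap_stats(rec, exclude_keypoints = "kp1")
  expect_equal(unname(st2$p_keypoint), c(0, 1, 1, 1) / 3)
})

test_that("gap stats survive a JSON round trip", {
  st <- known_gap_stats()
  p <- file.path(tempdir(), "gs.json")
  write_gap_stats(st, p)
  back <- read_gap_stats(p)
  expect_equal(back$p_keypoint, st$p_keypoint)
  expect_equal(back$gap_length_pmf, st$gap_length_pmf)
  expect_equal(back$intergap_pmf, st$intergap_pmf)
})

test_that("sampled gaps respect bounds and keypoint distributions", {
  st <- known_gap_stats()
  gaps <- with_seed(1, replicate(5000, sample_gaps(st, L = 60)[[1]], simplify = FALSE))
  kp <- sapply(gaps, `[[`, "keypoint")
  len <- sapply(gaps, `[[`, "length")
  start <- sapply(gaps, `[[`, "start")
  expect_true(all(len >= 1 & len <= 58))
  expect_true(all(start >= 2))
  expect_true(all(start + len - 1 <= 59))       # last frame stays observed
  freq <- tabulate(kp, 3) / length(kp)
  expect_true(all(abs(freq - c(0.5, 0.3, 0.2)) < 0.02))
  expect_true(all(len[kp == 3] == 4))           # one-length pmf on kp3
  one_hot <- known_gap_stats(p = c(0, 1, 0))
  g2 <- with_seed(2, replicate(50, sample_gaps(one_hot, 60)[[1]]$keypoint))
  expect_true(all(g2 == 2))
})

test_that("length pmfs are truncated and renormalized to [1, L-2]", {
  st <- known_gap_stats(lens = list(c(2, 40), c(3), c(4)))
  g <- with_seed(3, replicate(200, sample_gaps(st, L = 20)[[1]], simplify = FALSE))
  len <- sapply(g, `[[`, "length")
  kp <- sapply(g, `[[`, "keypoint")
  expect_true(all(len[kp == 1] == 2))  # 40 is impossible at L = 20
  expect_error(sample_gaps(st, L = 2), "at least 3")
})

test_that("multi-keypoint sampling draws distinct keypoints", {
  st <- known_gap_stats()
  g <- with_seed(4, sample_gaps(st, 60, n_missing = 3))
  expect_length(g, 3)
  expect_equal(anyDuplicated(sapply(g, `[[`, "keypoint")), 0)
  expect_error(sample_gaps(st, 60, n_missing = 4), "exceeds")
})

test_that("apply_gaps zero-fills exactly the masked cells and unmasking restores", {
  s <- preprocess_sample(rand_sample(L = 20, K = 4, D = 3, seed = 9))
  gaps <- list(list(keypoint = 2, start = 5, length = 6),
               list(keypoint = 2, start = 8, length = 5),   # overlap: merged
               list(keypoint = 4, start = 10, length = 3))
  m <- apply_gaps(s, gaps)
  expect_equal(sum(m$gap_mask), length(5:12) + 3)
  expect_true(all(m$input[masked_cells <- skelimpute:::masked_cells(m$gap_mask, 3)] == 0))
  expect_identical(m$target, s$coords)
  expect_arrays_equal(m$input[!masked_cells], m$target[!masked_cells], 0)
  restored <- m$input
  restored[masked_cells] <- m$target[masked_cells]
  expect_identical(restored, m$target)
  expect_equal(apply_gaps(s, list())$gap_mask, matrix(FALSE, 20, 4))
  incomplete <- s; incomplete$missing[1, 1] <- TRUE
  expect_error(apply_gaps(incomplete, gaps), "complete")
})

test_that("switch augmentation exchanges input only, never the target", {
  s <- preprocess_sample(rand_sample(L = 20, K = 4, D = 3, seed = 10))
  m <- apply_gaps(s, list(list(keypoint = 1, start = 5, length = 4)))
  m0 <- apply_switch(m, prob = 0)
  expect_identical(m0$input, m$input)
  expect_null(m0$switch_record)
  sw <- apply_switch(m, prob = 1, keypoints = c(1, 2), t_range = c(6, 16))
  expect_identical(sw$target, m$target)                  # loss target untouched
  expect_arrays_equal(sw$input[6:15, 1, ], m$input[6:15, 2, ], 0)
  expect_arrays_equal(sw$input[6:15, 2, ], m$input[6:15, 1, ], 0)
  expect_identical(sw$input[16:20, , ], m$input[16:20, , ])
  expect_identical(sw$input[1:5, , ], m$input[1:5, , ])
  expect_equal(unname(sw$switch_record[[1]]), c(1, 2, 6, 16))
})

test_that("sampled (keypoint, length) pairs match the configured pmfs (chi-square)", {
  st <- known_gap_stats(p = c(0.5, 0.3, 0.2),
                        lens = list(c(2, 5, 9), c(3, 7), c(4, 8, 12)))
  draws <- with_seed(11, replicate(10000, sample_gaps(st, 60)[[1]], simplify = FALSE))
  kp <- sapply(draws, `[[`, "keypoint")
  len <- sapply(draws, `[[`, "length")
  expect_gt(stats::chisq.test(tabulate(kp, 3), p = c(0.5, 0.3, 0.2))$p.value, 0.01)
  for (k in 1:3) {
    support <- as.integer(names(st$gap_length_pmf[[k]]))
    obs <- table(factor(len[kp == k], levels = support))
    expect_gt(stats::chisq.test(obs, p = st$gap_length_pmf[[k]])$p.value, 0.01)
  }
})
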