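test_that("csv round trip preserves coordinates, mask and metadata", {
  rec <- rand_recording(T = 5, K = 3, D = 3, seed = 11)
  rec$coords[2, 1, ] <- NaN
  rec <- skel_recording(rec$coords, rec$fps, rec$keypoint_names, id = "rt",
                        individual_of = c(1L, 1L, 2L))
  path <- file.path(tempdir(), "rt.csv")
  write_recording(rec, path, format = "csv")
  back <- load_recording(path, format = "csv")
  expect_arrays_equal(back$coords, rec$coords, 1e-9)
  expect_identical(back$missing, rec$missing)
  expect_identical(back$keypoint_names, rec$keypoint_names)
  expect_identical(back$individual_of, rec$individual_of)
  expect_equal(back$fps, rec$fps)

  # rds bundle is bit exact
  p2 <- file.path(tempdir(), "rt.rds")
  write_recording(rec, p2, format = "rds")
  back2 <- load_recording(p2, format = "rds")
  expect_identical(back2$coords, rec$coords)
  expect_identical(back2$missing, rec$missing)
})

test_that("fully observed csv loads with an all-false mask", {
  rec <- rand_recording(T = 3, K = 2, D = 2, seed = 1)
  path <- file.path(tempdir(), "obs.csv")
  write_recording(rec, path)
  back <- load_recording(path)
  expect_false(any(back$missing))
})

test_that("a NaN cell marks the whole keypoint-frame missing", {
  rec <- rand_recording(T = 3, K = 2, D = 2, seed = 2)
  co <- rec$coords
  co[2, 1, 1] <- NaN       # one axis only
  r2 <- skel_recording(co, 60)
  expect_true(r2$missing[2, 1])
  expect_true(all(is.na(r2$coords[2, 1, ])))
  expect_equal(sum(r2$missing), 1)
})

test_that("sentinel values are converted to missing on load", {
  rec <- rand_recording(T = 4, K = 2, D = 2, seed = 3)
  co <- rec$coords
  co[3, 2, ] <- -1
  path <- file.path(tempdir(), "sent.csv")
  write_recording(skel_recording(co, 60), path)
  back <- load_recording(path, missing_sentinel = -1)
  expect_true(back$missing[3, 2])
  expect_equal(sum(back$missing), 1)
})

test_that("pose_csv confidence thresholding masks exactly the low-confidence cells", {
  set.seed(4)
  Tn <- 20; K <- 3
  df <- data.frame(frame = 0:(Tn - 1))
  conf <- matrix(runif(Tn * K), Tn, K)
  for (k in seq_len(K)) {
    df[[paste0("kp", k, "_x")]] <- rnorm(Tn)
    df[[paste0("kp", k, "_y")]] <- rnorm(Tn)
    df[[paste0("kp", k, "_conf")]] <- conf[, k]
  }
  path <- file.path(tempdir(), "pose.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  th <- 0.5
  rec <- load_recording(path, format = "pose_csv", confidence_threshold = th)
  expect_identical(unname(rec$missing), unname(conf < th))  # direct scan oracle
  rec_all <- load_recording(path, format = "pose_csv")
  expect_false(any(rec_all$missing))
})

test_that("malformed headers and empty files error cleanly", {
  p <- file.path(tempdir(), "bad.csv")
  writeLines(c("a,b", "1,2"), p)
  expect_error(load_recording(p), "header")
  writeLines("frame,kp1_x,kp1_y,kp2_x", p)
  expect_error(load_recording(p), "frames|column")
})

test_that("by_time split partitions frames contiguously with floored bounds", {
  rec <- rand_recording(T = 1000, K = 2, D = 2, seed = 5)
  sp <- split_dataset(list(rec), c(0.7, 0.15, 0.15), mode = "by_time")
  expect_equal(n_frames <- sapply(sp, function(s) dim(s[[1]]$coords)[1]),
               c(train = 700, val = 150, test = 150))
  expect_equal(sp$train[[1]]$origin_start, 0)
  expect_equal(sp$val[[1]]$origin_start, 700)
  expect_equal(sp$test[[1]]$origin_start, 850)
  # train frames strictly precede val frames strictly precede test frames
  expect_lt(sp$train[[1]]$origin_start + 700 - 1, sp$val[[1]]$origin_start + 1)
  expect_arrays_equal(sp$val[[1]]$coords[1, , ], rec$coords[701, , ])
})

test_that("by_recording split is a seeded whole-recording partition", {
  recs <- lapply(1:10, function(i) rand_recording(T = 20, seed = i))
  sp <- split_dataset(recs, c(0.7, 0.15, 0.15), mode = "by_recording", seed = 3)
  ids <- lapply(sp, function(s) sapply(s, `[[`, "id"))
  expect_equal(lengths(ids), c(train = 7L, val = 1L, test = 2L))
  expect_equal(anyDuplicated(unlist(ids)), 0)
  sp2 <- split_dataset(recs, c(0.7, 0.15, 0.15), mode = "by_recording", seed = 3)
  expect_identical(ids, lapply(sp2, function(s) sapply(s, `[[`, "id")))
  expect_error(split_dataset(recs[1:2], mode = "by_recording"), "at least 3")
  expect_error(split_dataset(recs, c(0.5, 0.2, 0.2), mode = "by_recording"),
               "summing to 1")
})

test_that("extract_samples windows, stride and complete_only behave per contract", {
  rec <- rand_recording(T = 120, K = 3, D = 2, seed = 6)
  s <- extract_samples(rec, 60, 30)
  expect_length(s, 3)
  expect_equal(sapply(s, `[[`, "start_frame"), c(0, 30, 60))
  expect_length(extract_samples(rec, 60, 60), 2)

  co <- rec$coords; co[11, 2, ] <- NaN   # frame 10, 0-based
  rec2 <- skel_recording(co, 60, rec$keypoint_names)
  s2 <- extract_samples(rec2, 60, 30, complete_only = TRUE)
  expect_equal(sapply(s2, `[[`, "start_frame"), c(30, 60))

  expect_length(extract_samples(rand_recording(T = 30, seed = 1), 60, 30), 0)
})

test_that("sample missing counts add up to the recording's (window coverage)", {
  rec <- rand_recording(T = 100, K = 3, D = 3, seed = 7)
  co <- rec$coords
  drop <- with_seed(8, matrix(runif(300) < 0.07, 100, 3))
  for (d in 1:3) { p <- co[, , d]; p[drop] <- NaN; co[, , d] <- p }
  rec <- skel_recording(co, 60, rec$keypoint_names)
  s <- extract_samples(rec, 20, 20, complete_only = FALSE)  # exact tiling
  per_sample <- sum(sapply(s, function(x) sum(x$missing)))
  expect_equal(per_sample, sum(rec$missing))
})
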