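#' Fixed-length sample windows
#'
#' A `skel_sample` is an `L x K x D` window cut from a recording, carrying
#' the metadata needed to map model outputs back to original coordinates
#' (recording id, 0-based start frame, and -- after preprocessing -- the
#' transform parameters).
#'
#' @name skel_sample
NULL

new_sample <- function(coords, missing, recording_id, start_frame, fps,
                       keypoint_names, transform = NULL) {
  structure(list(coords = coords, missing = missing,
                 recording_id = recording_id, start_frame = start_frame,
                 length = dim(coords)[1], fps = fps,
                 keypoint_names = keypoint_names, dims = dim(coords)[3],
                 transform = transform),
            class = "skel_sample")
}

#' @export
print.skel_sample <- function(x, ...) {
  cat(sprintf("<skel_sample %s[%d:%d): %d x %d x %d, %d missing cells%s>\n",
              x$recording_id, x$start_frame, x$start_frame + x$length,
              x$length, length(x$keypoint_names), x$dims, sum(x$missing),
              if (is.null(x$transform)) "" else ", transformed"))
  invisible(x)
}

is_complete <- function(sample) !any(sample$missing)

#' Extract fixed-length samples from a recording
#'
#' Windows start at frames `0, stride, 2*stride, ...` (0-based, half-open
#' `[start, start + length)`). With `complete_only`, windows containing any
#' missing keypoint-frame are dropped -- only fully observed segments are
#' used for training and evaluation.
#'
#' @param recording a [skel_recording()].
#' @param length window length in frames (default 60).
#' @param stride shift between consecutive windows (default half a window).
#' @param complete_only drop windows with missing data.
#' @return list of `skel_sample` (empty when the recording is shorter than
#'   `length`).
#' @export
extract_samples <- function(recording, length = 60, stride = length %/% 2,
                            complete_only = FALSE) {
  L <- as.integer(length)
  if (L < 2) stop("sample length must be at least 2")
  if (stride < 1) stop("stride must be at least 1")
  Tn <- n_frames(recording)
  if (Tn < L) return(list())
  starts <- seq.int(0L, Tn - L, by = stride)
  out <- vector("list", base::length(starts))
  keep <- logical(base::length(starts))
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1L):(starts[i] + L)
    miss <- recording$missing[idx, , drop = FALSE]
    if (complete_only && any(miss)) next
    out[[i]] <- new_sample(recording$coords[idx, , , drop = FALSE], miss,
                           recording$id, starts[i], recording$fps,
                           recording$keypoint_names)
    keep[i] <- TRUE
  }
  out[keep]
}

#' Split recordings into train/validation/test sets
#'
#' Two modes mirror common practice in behavioral datasets:
#' \describe{
#'   \item{`by_recording`}{recordings are shuffled (seeded) and assigned
#'     whole, so no session is split across sets.}
#'   \item{`by_time`}{each recording is partitioned contiguously in temporal
#'     order, train then validation then test, so the train set only carries
#'     information prior to evaluation frames. Boundaries are floored:
#'     train gets frames `[0, floor(f1*T))`, validation
#'     `[floor(f1*T), floor((f1+f2)*T))`, test the remainder.}
#' }
#'
#' @param recordings list of [skel_recording()].
#' @param fractions length-3 numeric summing to 1, e.g. `c(0.7, 0.15, 0.15)`.
#' @param mode `"by_recording"` or `"by_time"`.
#' @param seed integer seed for the `by_recording` shuffle.
#' @return list with elements `train`, `val`, `test` (lists of recordings)
#'   and attributes `mode`, `fractions`.
#' @export
split_dataset <- function(recordings, fractions = c(0.7, 0.15, 0.15),
                          mode = c("by_recording", "by_time"), seed = 0) {
  mode <- match.arg(mode)
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_config("fractions must be three non-negative numbers summing to 1")
  }
  if (inherits(recordings, "skel_recording")) recordings <- list(recordings)
  if (mode == "by_recording") {
    n <- length(recordings)
    if (n < 3) stop_config("by_recording split requires at least 3 recordings")
    ord <- with_seed(seed, sample.int(n))
    n_train <- max(1L, floor(fractions[1] * n))
    n_val <- max(if (fractions[2] > 0) 1L else 0L, floor(fractions[2] * n))
    if (n_train + n_val >= n) n_train <- n - n_val - 1L
    sets <- list(train = recordings[ord[seq_len(n_train)]],
                 val = recordings[ord[n_train + seq_len(n_val)]],
                 test = recordings[ord[(n_train + n_val + 1L):n]])
  } else {
    sets <- list(train = list(), val = list(), test = list())
    for (rec in recordings) {
      Tn <- n_frames(rec)
      b1 <- floor(fractions[1] * Tn)
      b2 <- floor((fractions[1] + fractions[2]) * Tn)
      ranges <- list(train = c(0L, b1), val = c(b1, b2), test = c(b2, Tn))
      for (s in names(ranges)) {
        r <- ranges[[s]]
        if (r[2] <= r[1]) next
        idx <- (r[1] + 1L):r[2]
        sub <- skel_recording(rec$coords[idx, , , drop = FALSE], rec$fps,
                              rec$keypoint_names,
                              id = paste0(rec$id, ".", s),
                              individual_of = rec$individual_of,
                              missing = rec$missing[idx, , drop = FALSE])
        sub$origin_id <- rec$id
        sub$origin_start <- r[1]
        sets[[s]] <- c(sets[[s]], list(sub))
      }
    }
  }
  attr(sets, "mode") <- mode
  attr(sets, "fractions") <- fractions
  sets
}
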