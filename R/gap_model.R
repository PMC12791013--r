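#' Empirical missingness statistics
#'
#' Missingness in keypoint tracking is far from completely-at-random: which
#' keypoint drops out, for how long, and how often depends on the marker,
#' the task and the camera setup. `estimate_gap_stats()` summarises the
#' observed missingness process of a set of recordings with three
#' distributions, which the training-time gap sampler then mimics:
#' \itemize{
#'   \item `p_keypoint`: probability that a missing event hits keypoint k
#'     (proportional to the count of gap events on k; sums to 1),
#'   \item `gap_length_pmf`: per-keypoint distribution of gap lengths
#'     (a gap is a maximal run of consecutive missing frames),
#'   \item `intergap_pmf`: distribution of observed spacings between
#'     consecutive gaps on the same keypoint (pooled over keypoints).
#' }
#' Recordings with no missing data fall back to uniform distributions over
#' the eligible keypoints and over lengths `fallback_support`, so training
#' is possible on fully observed datasets too.
#'
#' @param recordings a [skel_recording()] or list of them.
#' @param exclude_keypoints keypoint names or indices whose `p_keypoint` is
#'   forced to 0 (e.g. near-rigid anchor keypoints not worth simulating).
#' @param fallback_support integer lengths used for uniform fallbacks
#'   (default `1:58`, matching the gap cap of 60-frame samples).
#' @return object of class `skel_gapstats`.
#' @export
estimate_gap_stats <- function(recordings, exclude_keypoints = NULL,
                               fallback_support = 1:58) {
  if (inherits(recordings, "skel_recording")) recordings <- list(recordings)
  if (length(recordings) == 0) stop("at least one recording is required")
  kp_names <- recordings[[1]]$keypoint_names
  K <- length(kp_names)
  if (is.character(exclude_keypoints)) {
    exclude_keypoints <- match(exclude_keypoints, kp_names)
  }
  eligible <- setdiff(seq_len(K), exclude_keypoints)
  ev_count <- integer(K)
  len_tab <- vector("list", K)
  intergaps <- integer(0)
  frames <- 0L
  for (rec in recordings) {
    frames <- frames + n_frames(rec)
    for (k in seq_len(K)) {
      r <- rle(rec$missing[, k])
      gl <- r$lengths[r$values]
      ev_count[k] <- ev_count[k] + length(gl)
      if (length(gl)) len_tab[[k]] <- c(len_tab[[k]], gl)
      # observed runs strictly between two gaps on this keypoint
      if (length(r$lengths) >= 3) {
        inner <- which(!r$values & seq_along(r$values) > 1 &
                         seq_along(r$values) < length(r$values))
        if (length(inner)) intergaps <- c(intergaps, r$lengths[inner])
      }
    }
  }
  ev_count[setdiff(seq_len(K), eligible)] <- 0L
  uniform_pmf <- stats::setNames(rep(1 / length(fallback_support),
                                     length(fallback_support)),
                                 fallback_support)
  p_kp <- if (sum(ev_count) > 0) ev_count / sum(ev_count) else {
    p <- numeric(K); p[eligible] <- 1 / length(eligible); p
  }
  names(p_kp) <- kp_names
  pmfs <- lapply(seq_len(K), function(k) {
    if (is.null(len_tab[[k]])) return(uniform_pmf)
    tb <- table(len_tab[[k]])
    stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  })
  names(pmfs) <- kp_names
  inter <- if (length(intergaps)) {
    tb <- table(intergaps)
    stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  } else uniform_pmf
  structure(list(p_keypoint = p_kp, gap_length_pmf = pmfs,
                 intergap_pmf = inter, source_frame_count = frames,
                 keypoint_names = kp_names),
            class = "skel_gapstats")
}

#' @export
print.skel_gapstats <- function(x, ...) {
  cat(sprintf("<skel_gapstats: %d keypoints, %d source frames>\n",
              length(x$p_keypoint), x$source_frame_count))
  print(round(x$p_keypoint, 3))
  invisible(x)
}

#' Serialize gap statistics to JSON
#' @param stats a `skel_gapstats`.
#' @param path output path.
#' @export
write_gap_stats <- function(stats, path) {
  x <- unclass(stats)
  # named vectors become JSON objects so probabilities keep their keys
  x$p_keypoint <- as.list(x$p_keypoint)
  x$gap_length_pmf <- lapply(x$gap_length_pmf, as.list)
  x$intergap_pmf <- as.list(x$intergap_pmf)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gap_stats
#' @export
read_gap_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$p_keypoint <- unlist(x$p_keypoint)
  x$gap_length_pmf <- lapply(x$gap_length_pmf, unlist)
  x$intergap_pmf <- unlist(x$intergap_pmf)
  structure(x, class = "skel_gapstats")
}

truncate_pmf <- function(pmf, support) {
  lens <- as.integer(names(pmf))
  keep <- lens %in% support
  if (!any(keep) || sum(pmf[keep]) <= 0) {
    return(stats::setNames(rep(1 / length(support), length(support)), support))
  }
  p <- pmf[keep] / sum(pmf[keep])
  p
}

sample_pmf <- function(pmf, n = 1) {
  as.integer(sample(names(pmf), n, replace = TRUE, prob = pmf))
}

#' Sample artificial gap specifications
#'
#' Draws `n_missing` distinct keypoints proportionally to `p_keypoint`
#' (without replacement), a length for each from its gap-length
#' distribution truncated to `[1, L - 2]` and renormalized, and a start
#' offset from the inter-gap distribution truncated to legal starts. The
#' first and last frame of a masked keypoint always stay observed, so a
#' linear-interpolation baseline remains applicable to every artificial gap.
#' Degenerate distributions fall back to uniform over the valid range.
#'
#' Sampling uses R's RNG stream: seed via `set.seed()` or [with_seed()]
#' upstream (the training loop threads explicit seeds through).
#'
#' @param stats a `skel_gapstats`.
#' @param L sample length in frames (must be >= 3).
#' @param n_missing number of simultaneously masked keypoints: a single
#'   integer, or an integer vector from which one count is drawn uniformly
#'   (e.g. `1:7` for the multi-keypoint regime).
#' @return list of gap specs `list(keypoint, start, length)` with 1-based
#'   `start >= 2` and `start + length - 1 <= L - 1`.
#' @export
sample_gaps <- function(stats, L, n_missing = 1) {
  L <- as.integer(L)
  if (L < 3) stop("sample length must be at least 3 to hold a gap")
  n <- if (length(n_missing) > 1) n_missing[sample.int(length(n_missing), 1)] else as.integer(n_missing)
  avail <- sum(stats$p_keypoint > 0)
  if (n > avail) stop_config("n_missing exceeds keypoints with positive missing probability")
  kps <- sample(seq_along(stats$p_keypoint), n, replace = FALSE,
                prob = stats$p_keypoint)
  lapply(kps, function(k) {
    lp <- truncate_pmf(stats$gap_length_pmf[[k]], 1:(L - 2))
    len <- sample_pmf(lp)
    valid_off <- 1:(L - 1 - len)
    op <- truncate_pmf(stats$intergap_pmf, valid_off)
    start <- 1L + sample_pmf(op)
    list(keypoint = k, start = start, length = len)
  })
}

#' Mask a complete sample with artificial gaps
#'
#' Training unit construction: the ground truth is kept as `target`, masked
#' cells are zero-filled in `input` (zero is an in-range value in normalized
#' coordinates, hence the separate binary mask), and `gap_mask` records
#' exactly which keypoint-frames were masked. Overlapping specs on the same
#' keypoint merge.
#'
#' @param sample a complete (no native missing), usually preprocessed
#'   [skel_sample].
#' @param gaps list of gap specs from [sample_gaps()].
#' @return object of class `skel_masked` with fields `input`, `gap_mask`,
#'   `target`, `switch_record` plus sample metadata.
#' @export
apply_gaps <- function(sample, gaps) {
  if (!is_complete(sample)) {
    stop("apply_gaps expects a complete sample (no native missing values)")
  }
  L <- sample$length; K <- length(sample$keypoint_names)
  gm <- matrix(FALSE, L, K)
  for (g in gaps) {
    idx <- g$start:(g$start + g$length - 1L)
    if (g$start < 2 || max(idx) > L - 1) stop("gap spec outside legal range")
    gm[idx, g$keypoint] <- TRUE
  }
  input <- sample$coords
  for (d in seq_len(sample$dims)) {
    plane <- input[, , d]
    plane[gm] <- 0
    input[, , d] <- plane
  }
  structure(list(input = input, gap_mask = gm, target = sample$coords,
                 switch_record = NULL, recording_id = sample$recording_id,
                 start_frame = sample$start_frame, fps = sample$fps,
                 keypoint_names = sample$keypoint_names, dims = sample$dims,
                 length = L, transform = sample$transform),
            class = "skel_masked")
}

#' @export
print.skel_masked <- function(x, ...) {
  cat(sprintf("<skel_masked %s[%d:%d): %d masked cells%s>\n", x$recording_id,
              x$start_frame, x$start_frame + x$length, sum(x$gap_mask),
              if (length(x$switch_record)) sprintf(", %d switch(es)", length(x$switch_record)) else ""))
  invisible(x)
}

#' Keypoint-switch data augmentation
#'
#' With probability `prob`, exchanges the *input* coordinates of two
#' distinct keypoints over a random sub-interval, emulating the identity
#' swaps that trackers produce when keypoints come close. The target is
#' never modified -- the loss is computed against the unswitched ground
#' truth, which is what teaches the model to undo switches. The applied
#' switch is recorded as `(kp_a, kp_b, t0, t1)` with half-open `[t0, t1)`.
#'
#' @param masked a `skel_masked`.
#' @param prob switch probability in `[0, 1]` (0.1 at training time;
#'   evaluation of switch robustness uses 0.5).
#' @param keypoints,t_range optional forced choice (two keypoint indices,
#'   and `c(t0, t1)`), bypassing the probability draw; used for testing and
#'   controlled evaluation.
#' @return the `skel_masked` with exchanged input and `switch_record` set.
#' @export
apply_switch <- function(masked, prob, keypoints = NULL, t_range = NULL) {
  K <- length(masked$keypoint_names)
  if (K < 2) return(masked)
  forced <- !is.null(keypoints)
  if (!forced && (prob <= 0 || stats::runif(1) >= prob)) return(masked)
  L <- masked$length
  if (is.null(keypoints)) keypoints <- sample.int(K, 2)
  if (is.null(t_range)) {
    t0 <- sample.int(L - 1, 1)
    t1 <- t0 + sample.int(L - t0, 1)
  } else {
    t0 <- t_range[1]; t1 <- t_range[2]
  }
  idx <- t0:(t1 - 1L)
  a <- keypoints[1]; b <- keypoints[2]
  tmp <- masked$input[idx, a, , drop = FALSE]
  masked$input[idx, a, ] <- masked$input[idx, b, , drop = FALSE]
  masked$input[idx, b, ] <- tmp
  masked$switch_record <- c(masked$switch_record,
                            list(c(kp_a = a, kp_b = b, t0 = t0, t1 = t1)))
  masked
}
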