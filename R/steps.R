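#' Smoothed ankle speed
#'
#' Instantaneous speed (per-frame Euclidean displacement times fps) of an
#' ankle trajectory, smoothed with a centred moving average spanning 0.1 s
#' (6 frames at 60 fps). Edges use partial windows. The input must be a
#' contiguous non-missing segment; callers split recordings at gaps.
#'
#' @param traj `T x D` matrix (or numeric vector for 1D traces) of ankle
#'   positions.
#' @param fps frames per second.
#' @param smooth_s smoothing span in seconds (default 0.1).
#' @return numeric vector of length `T`.
#' @export
ankle_speed <- function(traj, fps, smooth_s = 0.1) {
  if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
  if (anyNA(traj)) stop("ankle_speed requires a contiguous non-missing segment")
  Tn <- nrow(traj)
  if (Tn < 2) stop("need at least two frames")
  disp <- sqrt(rowSums(diff(traj)^2))
  speed <- c(disp[1], disp) * fps
  smooth_series(speed, max(1L, round(smooth_s * fps)))
}

# centred moving average with partial windows at the edges
smooth_series <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

accel_from_speed <- function(speed, fps, smooth_s = 0.1) {
  a <- c(diff(speed), 0) * fps
  smooth_series(a, max(1L, round(smooth_s * fps)))
}

# local maxima (plateau-aware, earliest frame wins) with topographic
# prominence: peak height minus the higher of the two flanking minima,
# where each flank extends to the nearest higher ground (or the boundary)
find_speed_peaks <- function(x, min_height, min_prominence, width_range_s, fps) {
  n <- length(x)
  out <- data.frame(peak = integer(0), height = numeric(0),
                    prominence = numeric(0), width_s = numeric(0))
  if (n < 3) return(out)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (i in seq_along(r$values)) {
    if (i == 1 || i == length(r$values)) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]) {
      cand <- c(cand, starts[i])   # earliest frame of a plateau peak
    }
  }
  for (p in cand) {
    h <- x[p]
    if (h < min_height) next
    i <- p
    lmin <- h
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < lmin) lmin <- x[i]
    }
    i <- p
    rmin <- h
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < rmin) rmin <- x[i]
    }
    prom <- h - max(lmin, rmin)
    if (prom < min_prominence) next
    # width at half prominence
    ref <- h - prom / 2
    a <- p
    while (a > 1 && x[a - 1] > ref) a <- a - 1
    b <- p
    while (b < n && x[b + 1] > ref) b <- b + 1
    width_s <- (b - a + 1) / fps
    if (width_s < width_range_s[1] || width_s > width_range_s[2]) next
    out <- rbind(out, data.frame(peak = p, height = h, prominence = prom,
                                 width_s = width_s, left_edge = a,
                                 right_edge = b))
  }
  out
}

#' Detect locomotor steps from an ankle speed profile
#'
#' A swing phase appears as a peak on the smoothed ankle speed. Candidate
#' peaks must clear a minimum height (default 20 units/s), a minimum
#' topographic prominence (21), and a width-at-half-prominence inside
#' 0.16-2 s. The swing start is then anchored at the acceleration *peak*
#' before the speed peak (takeoff) and the stop at the acceleration
#' *valley* after it (touchdown). Each anchor is the dominant acceleration
#' extremum within a window bounded by `search_s` seconds and by the speed
#' peak's own flanks (its width-at-half-prominence crossings plus a 0.5 s
#' margin), which keeps the anchoring robust to small acceleration ripples
#' on noisy plateaus. Peaks lacking either anchor are discarded, as are
#' steps whose start-to-stop interval is shorter than `min_step_duration`
#' (0.6 s) and -- when a height series is supplied -- steps whose ankle is
#' not lower at start and stop than during the swing.
#'
#' The default height/prominence values are calibrated for millimetre
#' units at 60 fps (mm/s); they are plain parameters because any other
#' unit system needs rescaled gates.
#'
#' @param speed smoothed speed series (see [ankle_speed()]).
#' @param accel acceleration series; derived from `speed` (first
#'   difference, same smoothing) when `NULL`.
#' @param fps frames per second.
#' @param min_height,min_prominence,peak_duration,min_step_duration,search_s
#'   detector gates.
#' @param height optional ankle height series (same length) for the
#'   position check.
#' @return data frame with 1-based frame indices `t_start`, `t_peak`,
#'   `t_stop`, plus `height`, `prominence`, `swing_duration` (s). Empty
#'   when nothing passes.
#' @export
detect_steps <- function(speed, accel = NULL, fps, min_height = 20,
                         min_prominence = 21, peak_duration = c(0.16, 2),
                         min_step_duration = 0.6, search_s = 2,
                         height = NULL) {
  accel <- accel %||% accel_from_speed(speed, fps)
  peaks <- find_speed_peaks(speed, min_height, min_prominence, peak_duration, fps)
  win <- round(search_s * fps)
  margin <- round(0.5 * fps)
  n <- length(speed)
  rows <- NULL
  for (i in seq_len(nrow(peaks))) {
    p <- peaks$peak[i]
    lo <- max(1L, p - win, peaks$left_edge[i] - margin)
    hi <- min(n, p + win, peaks$right_edge[i] + margin)
    if (lo >= p || hi <= p) next
    t_start <- lo - 1L + which.max(accel[lo:(p - 1L)])
    t_stop <- p + which.min(accel[(p + 1L):hi])
    if ((t_stop - t_start) / fps < min_step_duration) next
    if (!is.null(height) && t_stop - t_start >= 2) {
      interior <- max(height[(t_start + 1):(t_stop - 1)])
      if (!(height[t_start] < interior && height[t_stop] < interior)) next
    }
    rows <- rbind(rows, data.frame(t_start = t_start, t_peak = p,
                                   t_stop = t_stop, height = peaks$height[i],
                                   prominence = peaks$prominence[i],
                                   swing_duration = (t_stop - t_start) / fps))
  }
  if (is.null(rows)) {
    return(data.frame(t_start = integer(0), t_peak = integer(0),
                      t_stop = integer(0), height = numeric(0),
                      prominence = numeric(0), swing_duration = numeric(0)))
  }
  # two speed peaks inside one swing share anchors; keep the higher peak
  rows <- rows[order(rows$t_start, -rows$height), ]
  rows <- rows[!duplicated(rows[, c("t_start", "t_stop")]), ]
  rownames(rows) <- NULL
  rows
}

#' Swing-phase features of a detected step
#'
#' Stride length is the path length of the ankle trajectory between swing
#' start and stop (sum of per-frame displacement norms, at least the
#' straight-line chord); swing duration is the interval length in seconds.
#'
#' @param step one row of the [detect_steps()] output (or a list with
#'   `t_start`, `t_stop`).
#' @param traj `T x D` ankle trajectory in original units, non-missing over
#'   the step interval.
#' @param fps frames per second.
#' @return list with `stride_length` and `swing_duration`.
#' @export
step_features <- function(step, traj, fps) {
  if (is.null(dim(traj))) traj <- matrix(traj, ncol = 1)
  idx <- step$t_start:step$t_stop
  seg <- traj[idx, , drop = FALSE]
  if (anyNA(seg)) stop("step interval contains missing frames")
  list(stride_length = sum(sqrt(rowSums(diff(seg)^2))),
       swing_duration = (step$t_stop - step$t_start) / fps)
}

# run the detector over the contiguous observed segments of one keypoint
detect_steps_segments <- function(coords, missing_col, fps, height_axis = NULL, ...) {
  Tn <- nrow(coords)
  r <- rle(!missing_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- NULL
  for (i in which(r$values)) {
    if (r$lengths[i] < round(0.5 * fps)) next
    idx <- starts[i]:ends[i]
    seg <- coords[idx, , drop = FALSE]
    sp <- ankle_speed(seg, fps)
    ht <- if (!is.null(height_axis)) seg[, height_axis] else NULL
    st <- detect_steps(sp, fps = fps, height = ht, ...)
    if (nrow(st) == 0) next
    st$t_start <- st$t_start + starts[i] - 1L
    st$t_peak <- st$t_peak + starts[i] - 1L
    st$t_stop <- st$t_stop + starts[i] - 1L
    st$stride_length <- vapply(seq_len(nrow(st)), function(j) {
      step_features(st[j, ], coords, fps)$stride_length
    }, numeric(1))
    rows <- rbind(rows, st)
  }
  rows
}

#' Count steps before and after imputation
#'
#' Runs the same step detector on the contiguous observed segments of the
#' original recording and of its imputed version (whose segments are only
#' broken where cells are `still_missing`), returning counts and per-step
#' tables. This is the harness quantifying how much downstream kinematic
#' analysis recovers thanks to imputation: gaps fragment segments and hide
#' steps, imputation heals them.
#'
#' @param recording original [skel_recording()].
#' @param imputed a `skel_imputed` for the same recording.
#' @param ankles keypoint names (or indices) to treat as ankles, e.g.
#'   `c("left_ankle", "right_ankle")`.
#' @param height_axis coordinate axis used for the ankle-lower-at-start
#'   position check (default the last axis for 3D, none for 2D).
#' @param ... gate overrides passed to [detect_steps()].
#' @return list with `n_before`, `n_after`, `steps_before`, `steps_after`
#'   (data frames with a `side` column).
#' @export
count_steps_before_after <- function(recording, imputed, ankles,
                                     height_axis = NULL, ...) {
  if (is.character(ankles)) {
    ankles <- match(ankles, recording$keypoint_names)
    if (anyNA(ankles)) stop("unknown ankle keypoint name")
  }
  if (is.null(height_axis) && recording$dims == 3) height_axis <- 3
  run <- function(rec, miss) {
    rows <- NULL
    for (k in ankles) {
      st <- detect_steps_segments(matrix(rec$coords[, k, ], ncol = rec$dims),
                                  miss[, k], rec$fps,
                                  height_axis = height_axis, ...)
      if (!is.null(st) && nrow(st)) {
        st$side <- rec$keypoint_names[k]
        rows <- rbind(rows, st)
      }
    }
    rows %||% data.frame()
  }
  before <- run(recording, recording$missing)
  after <- run(imputed$recording, imputed$still_missing)
  list(n_before = nrow(before), n_after = nrow(after),
       steps_before = before, steps_after = after)
}
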