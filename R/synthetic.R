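#' Synthetic articulated-motion specification
#'
#' Generates test skeletons with known ground truth: a body centre follows
#' a smooth random-walk heading; keypoints are rigid body-frame offsets
#' plus sinusoidal limb oscillations (left/right antiphase for gait-like
#' motion) plus Gaussian noise. With two individuals, the second's centre
#' is attracted to the first with configurable strength, emulating
#' interacting-animal recordings.
#'
#' Presets:
#' \describe{
#'   \item{`mouse8`}{8 keypoints (hips, knees, ankles, back pairs), 3D,
#'     60 fps, millimetre scale; ankles/knees carry a 2 Hz antiphase gait
#'     oscillation. The body is elongated (~50 mm long, ~30 mm wide) as in
#'     a real rodent, which keeps the principal-axis heading well defined;
#'     near-isotropic skeletons should configure a heading keypoint pair
#'     instead. Matches the shape of floor-exploration mouse motion
#'     capture so configurations transfer.}
#'   \item{`fish2x3`}{2 individuals x 3 keypoints (head, fin, tail), 3D,
#'     60 fps, with centre-attraction coupling.}
#'   \item{`linear`}{keypoints drifting at exactly constant velocity with
#'     no oscillation and no noise: linear interpolation is exact on this
#'     fixture, which bounds any learned model from below.}
#' }
#'
#' @param preset `"mouse8"`, `"fish2x3"` or `"linear"`.
#' @param ... named overrides of spec fields (e.g. `noise_std`,
#'   `interaction_strength`, `noise_levels`).
#' @return object of class `skel_motionspec`.
#' @export
motion_spec <- function(preset = c("mouse8", "fish2x3", "linear"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    mouse8 = list(
      name = "mouse8", D = 3, fps = 60,
      keypoint_names = c("left_hip", "right_hip", "left_knee", "right_knee",
                         "left_ankle", "right_ankle", "left_back", "right_back"),
      individual_of = rep(1L, 8),
      offsets = rbind(c(-20, 12, 25), c(-20, -12, 25),
                      c(-25, 14, 15), c(-25, -14, 15),
                      c(-30, 15, 5), c(-30, -15, 5),
                      c(20, 8, 32), c(20, -8, 32)),
      amp = c(2, 2, 6, 6, 12, 12, 1.5, 1.5),
      freq = c(2, 2, 2, 2, 2, 2, 4, 4),
      phase = c(0, pi, 0, pi, 0, pi, 0, pi),
      osc_axis = rbind(c(0, 0, 1), c(0, 0, 1),
                       c(1, 0, 0.3), c(1, 0, 0.3),
                       c(1, 0, 0.5), c(1, 0, 0.5),
                       c(0, 0, 1), c(0, 0, 1)),
      drift_speed = 40, heading_sd = 0.03,
      interaction_strength = 0, noise_std = 0.5,
      noise_levels = NULL, noise_block = 60),
    fish2x3 = list(
      name = "fish2x3", D = 3, fps = 60,
      keypoint_names = c("head1", "fin1", "tail1", "head2", "fin2", "tail2"),
      individual_of = rep(1:2, each = 3),
      offsets = rbind(c(15, 0, 0), c(0, 4, 0), c(-15, 0, 0),
                      c(15, 0, 0), c(0, 4, 0), c(-15, 0, 0)),
      amp = c(1, 3, 8, 1, 3, 8),
      freq = c(2.5, 2.5, 2.5, 2.2, 2.2, 2.2),
      phase = c(0, 1, 2, 0.5, 1.5, 2.5),
      osc_axis = rbind(c(0, 1, 0.1), c(0, 1, 0.1), c(0, 1, 0.2),
                       c(0, 1, 0.1), c(0, 1, 0.1), c(0, 1, 0.2)),
      drift_speed = 60, heading_sd = 0.06,
      interaction_strength = 1.0, noise_std = 0.3,
      noise_levels = NULL, noise_block = 60),
    linear = list(
      name = "linear", D = 3, fps = 60,
      keypoint_names = c("left_hip", "right_hip", "left_knee", "right_knee",
                         "left_ankle", "right_ankle", "left_back", "right_back"),
      individual_of = rep(1L, 8),
      offsets = rbind(c(-15, 12, 25), c(-15, -12, 25),
                      c(-22, 15, 15), c(-22, -15, 15),
                      c(-28, 18, 5), c(-28, -18, 5),
                      c(5, 8, 32), c(5, -8, 32)),
      amp = rep(0, 8), freq = rep(1, 8), phase = rep(0, 8),
      osc_axis = matrix(rep(c(0, 0, 1), each = 8), ncol = 3),
      drift_speed = 40, heading_sd = 0,
      interaction_strength = 0, noise_std = 0,
      noise_levels = NULL, noise_block = 60))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$K <- length(base$keypoint_names)
  base$n_individuals <- length(unique(base$individual_of))
  if (any(base$freq >= base$fps / 2)) stop_config("oscillation frequency must be below Nyquist")
  structure(base, class = "skel_motionspec")
}

#' Simulate a complete recording
#'
#' Pure function of `(spec, T, seed)`. With `spec$noise_levels` set (a
#' vector of noise standard deviations), one level is drawn per
#' `noise_block` frames, producing the heteroscedastic regime used to
#' validate the estimated-error head: blocks differ in how predictable
#' they are.
#'
#' @param spec a [motion_spec()].
#' @param T number of frames.
#' @param seed RNG seed.
#' @return a complete [skel_recording()].
#' @export
simulate_recording <- function(spec, T = 3600, seed = 1) {
  with_seed(seed, {
    K <- spec$K; D <- spec$D
    n_ind <- spec$n_individuals
    centers <- array(0, c(T, n_ind, 3))
    headings <- matrix(0, T, n_ind)
    pos <- matrix(0, n_ind, 3)
    pos[, 1] <- seq(0, by = 80, length.out = n_ind)
    th <- stats::runif(n_ind, 0, 2 * pi)
    for (t in seq_len(T)) {
      th <- th + stats::rnorm(n_ind, 0, spec$heading_sd)
      v <- cbind(cos(th), sin(th), 0) * spec$drift_speed / spec$fps
      if (n_ind > 1 && spec$interaction_strength > 0) {
        for (i in 2:n_ind) {
          v[i, ] <- v[i, ] + spec$interaction_strength *
            (pos[1, ] - pos[i, ]) / spec$fps
        }
      }
      pos <- pos + v
      centers[t, , ] <- pos
      headings[t, ] <- th
    }
    noise_sd <- rep(spec$noise_std, T)
    if (!is.null(spec$noise_levels)) {
      nb <- ceiling(T / spec$noise_block)
      lv <- sample(spec$noise_levels, nb, replace = TRUE)
      noise_sd <- rep(lv, each = spec$noise_block)[seq_len(T)]
    }
    tt <- (seq_len(T) - 1) / spec$fps
    coords <- array(0, c(T, K, D))
    for (k in seq_len(K)) {
      ind <- spec$individual_of[k]
      ax <- spec$osc_axis[k, ] / sqrt(sum(spec$osc_axis[k, ]^2))
      osc <- spec$amp[k] * sin(2 * pi * spec$freq[k] * tt + spec$phase[k])
      local <- matrix(spec$offsets[k, ], T, 3, byrow = TRUE) + outer(osc, ax)
      hc <- cos(headings[, ind]); hs <- sin(headings[, ind])
      wx <- hc * local[, 1] - hs * local[, 2]
      wy <- hs * local[, 1] + hc * local[, 2]
      world <- cbind(wx, wy, local[, 3]) + centers[, ind, ]
      noise <- matrix(stats::rnorm(T * 3), T, 3) * noise_sd
      coords[, k, ] <- (world + noise)[, seq_len(D)]
    }
    skel_recording(coords, spec$fps, spec$keypoint_names,
                   id = paste0(spec$name, "_seed", seed),
                   individual_of = spec$individual_of)
  })
}

#' Inject synthetic missingness into a complete recording
#'
#' Places gap events (runs of missing frames) with a chosen keypoint
#' distribution and length distribution, mirroring what
#' [estimate_gap_stats()] later recovers. Events are placed without
#' overlap on the same keypoint (at least one observed frame separates two
#' gaps) by rejection sampling, and never touch the first or last frame.
#'
#' @param recording a complete [skel_recording()].
#' @param n_gaps number of gap events to place.
#' @param length_pmf named numeric vector: probability per gap length.
#' @param p_keypoint per-keypoint event probabilities (uniform if `NULL`).
#' @param seed RNG seed.
#' @return the recording with missing values (coords `NaN`, mask set).
#' @export
inject_missingness <- function(recording, n_gaps, length_pmf, p_keypoint = NULL,
                               seed = 1) {
  if (any(recording$missing)) stop("inject_missingness expects a complete recording")
  if (n_gaps == 0) return(recording)
  Tn <- n_frames(recording)
  K <- length(recording$keypoint_names)
  p_kp <- p_keypoint %||% rep(1 / K, K)
  lens <- as.integer(names(length_pmf))
  miss <- recording$missing
  with_seed(seed, {
    placed <- 0
    tries <- 0
    while (placed < n_gaps && tries < n_gaps * 200) {
      tries <- tries + 1
      k <- sample.int(K, 1, prob = p_kp)
      len <- lens[sample.int(length(lens), 1, prob = length_pmf)]
      if (len > Tn - 2) next
      s <- sample(2:(Tn - len), 1)
      idx <- s:(s + len - 1L)
      # keep a buffer frame so neighbouring gaps never merge
      window <- max(1, s - 1):min(Tn, s + len)
      if (any(miss[window, k])) next
      miss[idx, k] <- TRUE
      placed <- placed + 1
    }
    if (placed < n_gaps) {
      warning(sprintf("placed %d of %d requested gaps (recording saturated)",
                      placed, n_gaps))
    }
  })
  co <- recording$coords
  for (d in seq_len(recording$dims)) {
    plane <- co[, , d]
    plane[miss] <- NaN
    co[, , d] <- plane
  }
  skel_recording(co, recording$fps, recording$keypoint_names,
                 id = recording$id, individual_of = recording$individual_of,
                 missing = miss)
}

#' Synthetic ankle step trace
#'
#' One-dimensional ankle position whose speed profile is a low noise
#' baseline plus trapezoidal bumps (fast rise, plateau, fast fall). The
#' trapezoid shape is deliberate: the step detector anchors a step's start
#' at the acceleration peak (mid-rise) and its stop at the acceleration
#' valley (mid-fall), so the detectable interval of a bump equals its
#' nominal `step_duration` -- a smooth sinusoidal bump would be detected at
#' half its width and silently fail the minimum-duration gate.
#'
#' Ground truth records, per bump: analytic start/peak/stop frames, height,
#' duration, and whether the bump passes all detector gates (`valid`), so
#' recall and rejection can be scored exactly.
#'
#' @param n_steps number of bumps.
#' @param fps frames per second.
#' @param step_height bump heights, units/s (recycled; default 30, safely
#'   above the height-20 / prominence-21 gates).
#' @param step_duration nominal durations in seconds (recycled; default
#'   0.8 s, inside the 0.6 s minimum and the 0.16-2 s peak-width gate).
#' @param baseline_noise s.d. of the positive baseline speed noise.
#' @param rise_time rise/fall time of the trapezoid (s).
#' @param gap_between rest time between bumps (s).
#' @param seed RNG seed.
#' @param gates gate values used to annotate `valid` (defaults match
#'   [detect_steps()]).
#' @return list of class `skel_steptrace`: `position` (vector), `fps`,
#'   `truth` (data frame with 1-based frame indices `start`, `peak`,
#'   `stop`, plus `height`, `duration`, `valid`).
#' @export
make_step_trace <- function(n_steps, fps = 60, step_height = 30,
                            step_duration = 0.8, baseline_noise = 1,
                            rise_time = 0.15, gap_between = 1.2, seed = 1,
                            gates = list(min_height = 20, min_prominence = 21,
                                         peak_duration = c(0.16, 2),
                                         min_step_duration = 0.6)) {
  heights <- rep_len(step_height, max(n_steps, 1))
  durs <- rep_len(step_duration, max(n_steps, 1))
  widths <- durs + rise_time          # full bump support
  pad <- round(1.0 * fps)
  total <- pad
  bump_start <- integer(n_steps)
  if (n_steps > 0) {
    for (i in seq_len(n_steps)) {
      bump_start[i] <- total + 1L
      total <- total + round(widths[i] * fps) + round(gap_between * fps)
    }
  }
  total <- total + pad
  speed <- with_seed(seed, abs(stats::rnorm(total, 0, baseline_noise)))
  truth <- NULL
  rise_f <- round(rise_time * fps)
  for (i in seq_len(n_steps)) {
    w_f <- round(widths[i] * fps)
    j <- seq_len(w_f)
    # trapezoid, degrading to a (lower) triangle when too narrow to plateau
    prof <- heights[i] * pmin(1, j / rise_f, (w_f - j + 1) / rise_f)
    h_eff <- max(prof)
    idx <- bump_start[i]:(bump_start[i] + w_f - 1L)
    speed[idx] <- speed[idx] + prof
    t_start <- bump_start[i] + round(rise_f / 2)
    t_stop <- bump_start[i] + w_f - 1L - round(rise_f / 2)
    interval_s <- (t_stop - t_start) / fps
    width_s <- (w_f - rise_f) / fps   # width at half height ~ half prominence
    valid <- h_eff > gates$min_height &&
      h_eff > gates$min_prominence &&
      width_s >= gates$peak_duration[1] && width_s <= gates$peak_duration[2] &&
      interval_s >= gates$min_step_duration
    truth <- rbind(truth, data.frame(
      start = t_start, peak = bump_start[i] + w_f %/% 2, stop = t_stop,
      height = h_eff, duration = interval_s, valid = valid))
  }
  position <- cumsum(speed) / fps
  structure(list(position = position, fps = fps,
                 truth = truth %||% data.frame(start = integer(0),
                                               peak = integer(0),
                                               stop = integer(0),
                                               height = numeric(0),
                                               duration = numeric(0),
                                               valid = logical(0))),
            class = "skel_steptrace")
}
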