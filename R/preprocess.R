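#' View-invariant rotation of a sample
#'
#' Rotates the whole window about the z axis (and translates it) so that in
#' the middle frame the body sits at the origin and its dominant x-y heading
#' points along `(x = 1, y = 0)`. This removes absolute position and
#' orientation so models focus on intrinsic motion. No rotation is applied
#' in z. The transform parameters are stored on the sample for exact
#' inversion.
#'
#' The heading is either the vector between a configurable keypoint pair
#' (`pair = c(from, to)`, e.g. tail to head), or -- by default -- the first
#' principal axis of the middle-frame x-y keypoint cloud. A principal axis
#' has no inherent sign, so it is oriented to make its largest-magnitude
#' component positive.
#'
#' Degenerate middle frames (heading of zero length, or fewer than two
#' observed keypoints for the principal-axis rule) fall back to the identity
#' rotation and flag `degenerate = TRUE` in the transform.
#'
#' @param sample a [skel_sample]; the middle frame must have at least one
#'   observed keypoint.
#' @param heading `"principal_axis"` or `"pair"`.
#' @param pair keypoint names or indices `c(from, to)` when
#'   `heading = "pair"` (also used to orient the principal axis when given).
#' @return the sample with rotated coordinates and a `transform` entry.
#' @export
view_invariant_rotate <- function(sample, heading = c("principal_axis", "pair"),
                                  pair = NULL) {
  heading <- match.arg(heading)
  if (heading == "pair" && is.null(pair)) stop_config("heading = 'pair' requires `pair`")
  L <- sample$length; D <- sample$dims
  mid <- L %/% 2 + 1L
  obs <- !sample$missing[mid, ]
  if (!any(obs)) stop("middle frame has no observed keypoint; cannot orient sample")
  bary <- colMeans(matrix(sample$coords[mid, obs, ], nrow = sum(obs)))
  if (!is.null(pair) && is.character(pair)) {
    pair <- match(pair, sample$keypoint_names)
    if (any(is.na(pair))) stop_config("unknown keypoint in heading pair")
  }
  v <- NULL
  degenerate <- FALSE
  if (heading == "pair") {
    if (any(sample$missing[mid, pair])) {
      degenerate <- TRUE
    } else {
      v <- sample$coords[mid, pair[2], 1:2] - sample$coords[mid, pair[1], 1:2]
    }
  } else {
    if (sum(obs) < 2) {
      degenerate <- TRUE
    } else {
      xy <- matrix(sample$coords[mid, obs, ], nrow = sum(obs))[, 1:2, drop = FALSE]
      cv <- stats::cov(xy)
      if (!all(is.finite(cv)) || sum(cv^2) < 1e-24) {
        degenerate <- TRUE
      } else {
        e <- eigen(cv, symmetric = TRUE)$vectors[, 1]
        if (!is.null(pair) && !any(sample$missing[mid, pair])) {
          d <- sample$coords[mid, pair[2], 1:2] - sample$coords[mid, pair[1], 1:2]
          if (sum(e * d) < 0) e <- -e
        } else if (e[which.max(abs(e))] < 0) {
          e <- -e
        }
        v <- e
      }
    }
  }
  if (!degenerate && sqrt(sum(v^2)) < 1e-12) degenerate <- TRUE
  angle <- if (degenerate) 0 else atan2(v[2], v[1])
  co <- sample$coords
  for (d in seq_len(D)) co[, , d] <- co[, , d] - bary[d]
  if (angle != 0) {
    x <- co[, , 1]; y <- co[, , 2]
    co[, , 1] <- cos(-angle) * x - sin(-angle) * y
    co[, , 2] <- sin(-angle) * x + cos(-angle) * y
  }
  sample$coords <- co
  tr <- sample$transform %||% list()
  tr$barycenter <- bary
  tr$rotation_angle <- angle
  tr$degenerate <- degenerate
  sample$transform <- structure(tr, class = "skel_transform")
  sample
}

#' Min-max normalization of a sample
#'
#' Maps every coordinate into `[-1, 1]` per axis, with the per-axis minimum
#' and maximum taken over all *observed* keypoints and frames of the sample
#' (NaN cells are excluded and stay NaN). Normalization is per sample:
#' scaling is computed before any artificial masking, so inserted gaps never
#' influence the scale of the ground truth. A static axis (max equal to min,
#' e.g. a flat z) maps to 0 with the offset recorded, keeping the inverse
#' well defined.
#'
#' @param sample a [skel_sample] with at least one observed cell.
#' @return the sample with normalized coordinates and updated `transform`.
#' @export
minmax_normalize <- function(sample) {
  D <- sample$dims
  if (all(sample$missing)) stop("sample has no observed values")
  mn <- mx <- numeric(D)
  co <- sample$coords
  for (d in seq_len(D)) {
    vals <- co[, , d][!sample$missing]
    mn[d] <- min(vals); mx[d] <- max(vals)
    if (mx[d] > mn[d]) {
      co[, , d] <- 2 * (co[, , d] - mn[d]) / (mx[d] - mn[d]) - 1
    } else {
      plane <- co[, , d]
      plane[!is.na(plane)] <- 0
      co[, , d] <- plane
    }
  }
  sample$coords <- co
  tr <- sample$transform %||% list()
  tr$per_axis_min <- mn
  tr$per_axis_max <- mx
  sample$transform <- structure(tr, class = "skel_transform")
  sample
}

#' Rotate and normalize a sample
#'
#' Composition used throughout training and inference:
#' [view_invariant_rotate()] then [minmax_normalize()].
#' @inheritParams view_invariant_rotate
#' @export
preprocess_sample <- function(sample, heading = "principal_axis", pair = NULL) {
  minmax_normalize(view_invariant_rotate(sample, heading, pair))
}

#' Invert preprocessing
#'
#' Maps coordinates in normalized, view-invariant space back to the original
#' coordinate frame: un-scale, un-rotate, un-translate -- the exact inverse
#' of [preprocess_sample()] (round trips are exact to ~1e-12). Accepts a
#' sample (uses its own transform) or a raw `L x K x D` array plus a
#' transform, which is how model predictions are returned to original units.
#'
#' @param x a transformed [skel_sample] or an `L x K x D` array.
#' @param transform a `skel_transform`; taken from `x` when omitted.
#' @return object of the same kind as `x`, in original coordinates.
#' @export
inverse_transform <- function(x, transform = NULL) {
  is_sample <- inherits(x, "skel_sample")
  co <- if (is_sample) x$coords else x
  tr <- transform %||% (if (is_sample) x$transform else NULL)
  if (is.null(tr)) stop("no transform available")
  if (length(dim(co)) != 3) stop("coordinates must be an L x K x D array")
  D <- dim(co)[3]
  if (!is.null(tr$per_axis_min)) {
    for (d in seq_len(D)) {
      mn <- tr$per_axis_min[d]; mx <- tr$per_axis_max[d]
      co[, , d] <- if (mx > mn) (co[, , d] + 1) / 2 * (mx - mn) + mn else {
        plane <- co[, , d]
        plane[!is.na(plane)] <- mn
        plane
      }
    }
  }
  a <- tr$rotation_angle %||% 0
  if (a != 0) {
    x1 <- co[, , 1]; y1 <- co[, , 2]
    co[, , 1] <- cos(a) * x1 - sin(a) * y1
    co[, , 2] <- sin(a) * x1 + cos(a) * y1
  }
  if (!is.null(tr$barycenter)) {
    for (d in seq_len(D)) co[, , d] <- co[, , d] + tr$barycenter[d]
  }
  if (is_sample) {
    x$coords <- co
    x$transform <- NULL
    x
  } else {
    co
  }
}
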