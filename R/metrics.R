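#' Imputation error metrics on masked cells
#'
#' All metrics are computed only on keypoint-frames flagged in `gap_mask`;
#' errors on observed (or unmasked) cells never contribute. `N` counts
#' masked keypoint-frame *positions*, not scalar coordinates, so a single
#' 3D point off by (3, 4, 0) gives RMSE = MPJPE = 5.
#'
#' \describe{
#'   \item{`rmse`}{`sqrt(1/N * sum over masked (k, t) of squared coordinate
#'     differences summed over axes)`.}
#'   \item{`mpjpe`}{mean per-joint position error: the mean over masked
#'     positions of the Euclidean distance between prediction and truth.
#'     Always `<=` RMSE (Jensen), with equality iff all distances equal.}
#'   \item{`pck`}{percentage of correct keypoints: the fraction of masked
#'     positions with distance strictly below `th * max_dist`, where
#'     `max_dist` is the dataset-wide maximum inter-keypoint distance (see
#'     [max_interkeypoint_distance()]). A strict threshold of `th = 0.01`
#'     (1% of the body scale) is the default reported.}
#' }
#'
#' Units follow the input arrays; method comparisons are done after
#' [inverse_transform()] to original coordinates.
#'
#' @param pred,gt `L x K x D` arrays (or `T x K x D`).
#' @param gap_mask matching `L x K` logical with at least one `TRUE`.
#' @param th PCK threshold fraction in (0, 1).
#' @param max_dist dataset maximum inter-keypoint distance (same units).
#' @return scalar metric value.
#' @export
rmse <- function(pred, gt, gap_mask) {
  sqrt(mean(sq_dists(pred, gt, gap_mask)))
}

#' @rdname rmse
#' @export
mpjpe <- function(pred, gt, gap_mask) {
  mean(sqrt(sq_dists(pred, gt, gap_mask)))
}

#' @rdname rmse
#' @export
pck <- function(pred, gt, gap_mask, th = 0.01, max_dist) {
  if (max_dist <= 0) stop("max_dist must be positive")
  d <- sqrt(sq_dists(pred, gt, gap_mask))
  mean(d < th * max_dist)
}

sq_dists <- function(pred, gt, gap_mask) {
  if (sum(gap_mask) < 1) stop("metrics are undefined without masked positions")
  D <- dim(pred)[3]
  sq <- matrix(0, dim(pred)[1], dim(pred)[2])
  for (d in seq_len(D)) sq <- sq + (pred[, , d] - gt[, , d])^2
  sq[gap_mask]
}

#' Dataset maximum inter-keypoint distance
#'
#' The largest Euclidean distance between any two (observed) keypoints in
#' any frame, across all given recordings -- the body-scale reference used
#' by the PCK threshold.
#'
#' @param recordings a [skel_recording()] or list of them.
#' @return positive scalar (original units).
#' @export
max_interkeypoint_distance <- function(recordings) {
  if (inherits(recordings, "skel_recording")) recordings <- list(recordings)
  best <- -Inf
  for (rec in recordings) {
    K <- length(rec$keypoint_names)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        ok <- !rec$missing[, i] & !rec$missing[, j]
        if (!any(ok)) next
        sq <- 0
        for (d in seq_len(rec$dims)) {
          sq <- sq + (rec$coords[ok, i, d] - rec$coords[ok, j, d])^2
        }
        best <- max(best, max(sq))
      }
    }
  }
  if (!is.finite(best)) stop("no frame with an observed keypoint pair")
  sqrt(best)
}

#' Movement of a sample
#'
#' Averaged absolute frame-to-frame difference over every coordinate of
#' every keypoint; 0 for a static sample. Defined on complete samples only.
#'
#' @param sample a complete [skel_sample] (or `L x K x D` array).
#' @export
movement <- function(sample) {
  co <- if (inherits(sample, "skel_sample")) sample$coords else sample
  if (anyNA(co)) stop("movement is defined on sequences without missing data")
  if (dim(co)[1] < 2) stop("need at least two frames")
  mean(abs(apply(co, c(2, 3), diff)))
}

#' Periodicity of a sample
#'
#' The largest non-DC magnitude in the discrete Fourier spectrum of any
#' single coordinate series of the sample (amplitude units: a pure
#' sinusoid of amplitude a scores a). The DC component is excluded --
#' otherwise any offset would dominate -- so a constant sample scores 0.
#'
#' @inheritParams movement
#' @export
periodicity <- function(sample) {
  co <- if (inherits(sample, "skel_sample")) sample$coords else sample
  if (anyNA(co)) stop("periodicity is defined on sequences without missing data")
  L <- dim(co)[1]
  nfreq <- floor(L / 2)
  if (nfreq < 1) stop("sample too short for a spectrum")
  best <- 0
  for (k in seq_len(dim(co)[2])) {
    for (d in seq_len(dim(co)[3])) {
      sp <- Mod(stats::fft(co[, k, d]))[2:(nfreq + 1)]
      best <- max(best, 2 * sp / L)
    }
  }
  best
}

#' Evaluate a model on masked samples in original units
#'
#' Convenience wrapper: inverse-transforms predictions and targets of a
#' list of masked samples and pools RMSE / MPJPE / PCK over all masked
#' positions.
#'
#' @param predictions list of `skel_prediction` (from [predict.skel_imputer()]).
#' @param masked matching list of `skel_masked` carrying transforms.
#' @param max_dist for PCK; skipped when `NULL`.
#' @param th PCK threshold.
#' @return one-row data frame with `rmse`, `mpjpe`, `pck`, `n_missing`.
#' @export
evaluate_imputation <- function(predictions, masked, max_dist = NULL, th = 0.01) {
  sq_all <- numeric(0)
  for (i in seq_along(predictions)) {
    m <- masked[[i]]
    pr <- inverse_transform(predictions[[i]]$mean, m$transform)
    gt <- inverse_transform(m$target, m$transform)
    sq_all <- c(sq_all, sq_dists(pr, gt, m$gap_mask))
  }
  data.frame(rmse = sqrt(mean(sq_all)), mpjpe = mean(sqrt(sq_all)),
             pck = if (is.null(max_dist)) NA_real_ else mean(sqrt(sq_all) < th * max_dist),
             n_missing = length(sq_all))
}
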