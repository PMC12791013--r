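#' Linear-interpolation baseline
#'
#' Fills each gap independently per keypoint and axis by straight-line
#' interpolation between the observed anchor frames on both sides -- the
#' ubiquitous baseline in behavioral science. Gaps without an anchor on
#' either side (leading/trailing) are left missing. Observed coordinates
#' are bit-identical in the output.
#'
#' @param recording a [skel_recording()].
#' @return object of class `skel_imputed`: fields `recording` (imputed),
#'   `still_missing` (`T x K` logical), `per_window_error` (empty for this
#'   method), `method`.
#' @export
linear_interpolate <- function(recording) {
  Tn <- n_frames(recording)
  K <- length(recording$keypoint_names)
  co <- recording$coords
  for (k in seq_len(K)) {
    obs <- !recording$missing[, k]
    if (sum(obs) < 2 || all(obs)) next
    for (d in seq_len(recording$dims)) {
      y <- co[, k, d]
      filled <- stats::approx(which(obs), y[obs], xout = seq_len(Tn),
                              method = "linear", rule = 1)$y
      filled[obs] <- y[obs]
      co[, k, d] <- filled
    }
  }
  still <- apply(is.na(co), c(1, 2), any)
  out <- skel_recording(co, recording$fps, recording$keypoint_names,
                        id = recording$id, individual_of = recording$individual_of,
                        missing = still)
  structure(list(recording = out, still_missing = still,
                 per_window_error = empty_window_df(),
                 method = "linear_interpolation"),
            class = "skel_imputed")
}

empty_window_df <- function() {
  data.frame(start_frame = integer(0), estimated_error = numeric(0),
             accepted = logical(0), reason = character(0))
}

#' @export
print.skel_imputed <- function(x, ...) {
  cat(sprintf("<skel_imputed (%s): %d cells still missing>\n",
              x$method, sum(x$still_missing)))
  invisible(x)
}

#' Estimated error of a prediction
#'
#' The mean predicted standard deviation over a sample's masked cells
#' (normalized units) -- a per-sample confidence proxy that correlates with
#' the true imputation error and drives quality filtering.
#'
#' @param prediction a `skel_prediction` from a probabilistic model.
#' @param gap_mask `L x K` logical; defaults to the prediction's own mask.
#' @return non-negative scalar.
#' @export
estimated_error <- function(prediction, gap_mask = NULL) {
  if (is.null(prediction$std)) {
    stop("estimated error requires a probabilistic model (no std available)")
  }
  gm <- gap_mask %||% prediction$gap_mask
  if (is.null(gm) || !any(gm)) stop("no masked cells to estimate error on")
  mean(prediction$std[masked_cells(gm, dim(prediction$std)[3])])
}

#' Filter imputation results by estimated error
#'
#' Keeps results whose estimated error is at or below `threshold`.
#' Accepts a numeric vector of errors (returns a logical vector) or a list
#' of objects with an `error` field (returns the accepted subset).
#'
#' @param results numeric vector or list.
#' @param threshold acceptance threshold (same normalized units as the
#'   estimated error; 0.1 is the default working point for full-recording
#'   imputation).
#' @export
filter_by_error <- function(results, threshold) {
  if (is.numeric(results)) return(results <= threshold)
  keep <- vapply(results, function(r) r$error <= threshold, logical(1))
  results[keep]
}

#' Impute a whole recording with a trained model
#'
#' Tiles the recording with model-length windows so that every native gap
#' that can be imputed is centred in some window (shifted at recording
#' edges), preprocesses each window on its observed cells, predicts, and
#' writes accepted predictions back in original coordinates. Windows are
#' rejected -- leaving their gaps missing -- when
#' \itemize{
#'   \item a gap run is longer than `L - 2` frames (prohibitively long: the
#'     model is never trained beyond that, and no recursive forecasting is
#'     attempted),
#'   \item a gap touches the recording edge with no observed frame on one
#'     side,
#'   \item more keypoints are missing simultaneously than the model was
#'     trained for (`max_simultaneous`),
#'   \item the window cannot be oriented (fully missing middle frame), or
#'   \item (probabilistic models) the estimated error exceeds
#'     `error_threshold`.
#' }
#' When two accepted windows impute the same cell, their original-unit
#' predictions are averaged, weighted by inverse squared estimated error
#' when available -- deterministic and seam-free. Observed coordinates are
#' never altered.
#'
#' @param model a trained `skel_imputer`.
#' @param recording a [skel_recording()] with matching `K` and `D`.
#' @param error_threshold acceptance threshold on the estimated error
#'   (normalized units); `Inf` accepts everything. Default 0.1.
#' @param max_simultaneous maximum simultaneously missing keypoints per
#'   frame a window may contain; defaults to what the model was trained
#'   for.
#' @param batch_size forward-pass batch size.
#' @return a `skel_imputed` (see [linear_interpolate()]) whose
#'   `per_window_error` table reports each window's 0-based start,
#'   estimated error and acceptance.
#' @export
impute_recording <- function(model, recording, error_threshold = 0.1,
                             max_simultaneous = NULL, batch_size = 32) {
  stopifnot(inherits(model, "skel_imputer"), inherits(recording, "skel_recording"))
  cfg <- model$config
  if (length(recording$keypoint_names) != cfg$K || recording$dims != cfg$D) {
    stop("recording shape does not match the model configuration")
  }
  L <- cfg$L
  Tn <- n_frames(recording)
  K <- cfg$K
  max_sim <- max_simultaneous %||%
    (if (is.na(model$n_missing_trained)) K - 1L else model$n_missing_trained)

  if (!any(recording$missing) || Tn < L) {
    return(structure(list(recording = recording,
                          still_missing = recording$missing,
                          per_window_error = empty_window_df(),
                          method = paste0(model$backbone, "_imputer")),
                     class = "skel_imputed"))
  }

  # gap runs per keypoint; each imputable run requests one window centred
  # on it, with margins so an observed frame borders the gap on both sides
  windows <- list()
  win_runs <- list()
  skipped <- empty_window_df()
  for (k in seq_len(K)) {
    r <- rle(recording$missing[, k])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      a <- starts[i]; b <- ends[i]
      if (b - a + 1L > L - 2L) {
        skipped <- rbind(skipped, data.frame(start_frame = a - 1L,
                                             estimated_error = NA_real_,
                                             accepted = FALSE, reason = "gap_too_long"))
        next
      }
      lo <- max(1L, b - L + 2L)
      hi <- min(a - 1L, Tn - L + 1L)
      if (lo > hi) {
        skipped <- rbind(skipped, data.frame(start_frame = a - 1L,
                                             estimated_error = NA_real_,
                                             accepted = FALSE, reason = "gap_at_edge"))
        next
      }
      w <- min(max(round((a + b) / 2 - L / 2), lo), hi)
      key <- as.character(w)
      windows[[key]] <- w
      win_runs[[key]] <- rbind(win_runs[[key]], c(k, a, b))
    }
  }

  co <- recording$coords
  wsum <- array(0, dim(co))
  wwt <- array(0, dim(co))
  per_window <- skipped
  win_starts <- sort(unlist(windows))
  pend <- list()
  for (w in win_starts) {
    idx <- w:(w + L - 1L)
    miss <- recording$missing[idx, , drop = FALSE]
    if (max(rowSums(miss)) > max_sim) {
      per_window <- rbind(per_window, data.frame(start_frame = w - 1L,
                                                 estimated_error = NA_real_,
                                                 accepted = FALSE,
                                                 reason = "too_many_simultaneous"))
      next
    }
    samp <- new_sample(recording$coords[idx, , , drop = FALSE], miss,
                       recording$id, w - 1L, recording$fps,
                       recording$keypoint_names)
    if (all(samp$missing[L %/% 2 + 1L, ])) {
      per_window <- rbind(per_window, data.frame(start_frame = w - 1L,
                                                 estimated_error = NA_real_,
                                                 accepted = FALSE,
                                                 reason = "unorientable"))
      next
    }
    pp <- preprocess_sample(samp, model$preprocess$heading, model$preprocess$pair)
    input <- pp$coords
    input[is.na(input)] <- 0
    mk <- structure(list(input = input, gap_mask = miss, target = pp$coords,
                         switch_record = NULL, recording_id = recording$id,
                         start_frame = w - 1L, fps = recording$fps,
                         keypoint_names = recording$keypoint_names,
                         dims = cfg$D, length = L, transform = pp$transform),
                    class = "skel_masked")
    pend[[length(pend) + 1L]] <- list(w = w, masked = mk)
  }

  if (length(pend)) {
    preds <- predict(model, lapply(pend, `[[`, "masked"), batch_size = batch_size)
    for (j in seq_along(pend)) {
      w <- pend[[j]]$w
      mk <- pend[[j]]$masked
      pr <- preds[[j]]
      err <- if (cfg$proba) estimated_error(pr, mk$gap_mask) else NA_real_
      accepted <- !cfg$proba || err <= error_threshold
      per_window <- rbind(per_window,
                          data.frame(start_frame = w - 1L, estimated_error = err,
                                     accepted = accepted,
                                     reason = if (accepted) "" else "error_above_threshold"))
      if (!accepted) next
      orig <- inverse_transform(pr$mean, mk$transform)
      wt <- if (cfg$proba) 1 / (err^2 + 1e-12) else 1
      idx <- w:(w + L - 1L)
      # fill only cells of the runs assigned to this window
      runs <- win_runs[[as.character(w)]]
      for (r in seq_len(nrow(runs))) {
        k <- runs[r, 1]; fa <- runs[r, 2]; fb <- runs[r, 3]
        loc <- (fa:fb) - w + 1L
        for (d in seq_len(cfg$D)) {
          wsum[fa:fb, k, d] <- wsum[fa:fb, k, d] + wt * orig[loc, k, d]
          wwt[fa:fb, k, d] <- wwt[fa:fb, k, d] + wt
        }
      }
    }
  }

  filled <- wwt[, , 1] > 0
  for (d in seq_len(cfg$D)) {
    plane <- co[, , d]
    plane[filled] <- (wsum[, , d] / wwt[, , d])[filled]
    co[, , d] <- plane
  }
  still <- recording$missing & !filled
  out <- skel_recording(co, recording$fps, recording$keypoint_names,
                        id = recording$id,
                        individual_of = recording$individual_of,
                        missing = still)
  rownames(per_window) <- NULL
  structure(list(recording = out, still_missing = still,
                 per_window_error = per_window[order(per_window$start_frame), ],
                 method = paste0(model$backbone, "_imputer")),
            class = "skel_imputed")
}
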