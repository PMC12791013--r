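#' Keypoint trajectory recording
#'
#' A `skel_recording` holds one tracking session: a `T x K x D` coordinate
#' array (original units), a `T x K` logical missingness mask, the frame
#' rate and the keypoint names. Missing keypoint-frames are stored as `NaN`
#' in all `D` coordinates and flagged in the mask; a keypoint-frame with any
#' unobserved coordinate is treated as wholly missing, since 2D/3D keypoint
#' coordinates are estimated jointly and a lone surviving axis is
#' untrustworthy. Zero is a legal coordinate value, so `NaN` (never zero)
#' is the internal sentinel; zero-filling happens only when model inputs
#' are assembled.
#'
#' @param coords numeric `T x K x D` array (`D` of 2 or 3).
#' @param fps frames per second, positive.
#' @param keypoint_names character vector of length `K` (generated if `NULL`).
#' @param id recording identifier string.
#' @param individual_of optional length-`K` vector of individual labels for
#'   multi-animal data.
#' @param missing optional `T x K` logical mask; derived from `NaN`/`NA`
#'   cells when omitted.
#' @return object of class `skel_recording`.
#' @export
skel_recording <- function(coords, fps, keypoint_names = NULL, id = "recording",
                           individual_of = NULL, missing = NULL) {
  if (length(dim(coords)) != 3) stop("coords must be a T x K x D array")
  Tn <- dim(coords)[1]; K <- dim(coords)[2]; D <- dim(coords)[3]
  if (Tn < 1) stop("recording has zero frames")
  if (K < 2) stop("at least two keypoints are required")
  if (!D %in% c(2, 3)) stop("D must be 2 or 3")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (is.null(keypoint_names)) keypoint_names <- paste0("kp", seq_len(K))
  if (length(keypoint_names) != K) stop("keypoint_names length must equal K")
  derived <- apply(is.na(coords), c(1, 2), any)
  if (is.null(missing)) {
    missing <- derived
  } else {
    missing <- missing | derived
  }
  # enforce: a missing keypoint-frame has all D coordinates NaN
  for (d in seq_len(D)) {
    plane <- coords[, , d, drop = FALSE]
    dim(plane) <- c(Tn, K)
    plane[missing] <- NaN
    coords[, , d] <- plane
  }
  if (any(!is.finite(coords[, , 1][!missing]))) {
    stop("coords must be finite wherever not missing")
  }
  if (!is.null(individual_of) && length(individual_of) != K) {
    stop("individual_of must have one entry per keypoint")
  }
  structure(list(id = id, fps = fps, keypoint_names = keypoint_names,
                 dims = D, coords = coords, missing = missing,
                 individual_of = individual_of),
            class = "skel_recording")
}

#' @export
print.skel_recording <- function(x, ...) {
  Tn <- dim(x$coords)[1]
  miss <- sum(x$missing)
  cat(sprintf("<skel_recording '%s': %d frames, %d keypoints, %dD, %g fps, %.1f%% missing>\n",
              x$id, Tn, length(x$keypoint_names), x$dims, x$fps,
              100 * miss / length(x$missing)))
  invisible(x)
}

n_frames <- function(rec) dim(rec$coords)[1]

axis_names <- function(D) c("x", "y", "z")[seq_len(D)]

#' Load a keypoint trajectory from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{header `frame,<kp>_x,<kp>_y[,<kp>_z],...`, comma separated;
#'     missing cells as `NA`/`NaN` or a numeric sentinel. A JSON metadata
#'     sidecar `<path>.json` (written by [write_recording()]) is read when
#'     present, providing fps and individual labels.}
#'   \item{`pose_csv`}{as `csv` with an additional `<kp>_conf` confidence
#'     column per keypoint (pose-estimator exports); coordinates whose
#'     confidence falls below `confidence_threshold` are marked missing.}
#'   \item{`rds`}{array bundle written by [write_recording()]; exact
#'     round trip including the mask.}
#' }
#'
#' @param path file path.
#' @param format one of `"csv"`, `"pose_csv"`, `"rds"`.
#' @param fps frames per second; overrides any sidecar metadata. Default 60.
#' @param missing_sentinel value marking missing coordinates in addition to
#'   `NA`/`NaN` (e.g. 0 for trackers that emit zeros), or `NULL`.
#' @param confidence_threshold for `pose_csv`: keypoint-frames with
#'   confidence strictly below this are marked missing; `NULL` keeps all.
#' @param id recording id; defaults to the file name.
#' @return a [skel_recording()].
#' @export
load_recording <- function(path, format = c("csv", "pose_csv", "rds"), fps = NULL,
                           missing_sentinel = NULL, confidence_threshold = NULL,
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "rds") {
    b <- readRDS(path)
    return(skel_recording(b$coords, fps %||% b$fps, b$keypoint_names,
                          id = b$id %||% id, individual_of = b$individual_of,
                          missing = b$missing))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("recording file has zero frames: ", path)
  hdr <- names(df)
  if (hdr[1] != "frame") stop("malformed header: first column must be 'frame'")
  cols <- hdr[-1]
  suff <- sub("^.*_", "", cols)
  base <- sub("_[a-z]+$", "", cols)
  known <- c("x", "y", "z", "conf")
  if (!all(suff %in% known)) {
    stop("malformed header: coordinate columns must end in _x/_y/_z", if (format == "pose_csv") "/_conf")
  }
  kp <- unique(base)
  D <- if (any(suff == "z")) 3L else 2L
  has_conf <- any(suff == "conf")
  if (format == "csv" && has_conf) stop("confidence columns present; use format = 'pose_csv'")
  want <- c(axis_names(D), if (format == "pose_csv") "conf")
  expect <- as.vector(t(outer(kp, want, paste, sep = "_")))
  if (!identical(cols, expect)) {
    stop("inconsistent column count or order: expected ", length(expect),
         " coordinate columns (", length(kp), " keypoints x ", length(want), ")")
  }
  Tn <- nrow(df); K <- length(kp)
  coords <- array(NA_real_, c(Tn, K, D))
  for (k in seq_len(K)) {
    for (d in seq_len(D)) {
      coords[, k, d] <- df[[paste0(kp[k], "_", axis_names(D)[d])]]
    }
  }
  if (!is.null(missing_sentinel) && !is.na(missing_sentinel)) {
    coords[coords == missing_sentinel] <- NaN
  }
  if (format == "pose_csv" && !is.null(confidence_threshold)) {
    for (k in seq_len(K)) {
      conf <- df[[paste0(kp[k], "_conf")]]
      low <- !is.na(conf) & conf < confidence_threshold
      if (any(low)) coords[low, k, ] <- NaN
    }
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  skel_recording(coords, fps %||% meta$fps %||% 60, kp, id = meta$id %||% id,
                 individual_of = unlist(meta$individual_of) %||% NULL)
}

#' Write a recording to disk
#'
#' `csv` writes the dialect read by [load_recording()] plus a JSON metadata
#' sidecar (`<path>.json`: fps, keypoint names, individual labels) so the
#' round trip preserves everything but at text precision; `rds` is an exact
#' binary bundle.
#'
#' @param recording a [skel_recording()].
#' @param path output path.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(recording[c("coords", "missing", "fps", "keypoint_names",
                        "individual_of", "id")], path)
    return(invisible(path))
  }
  Tn <- n_frames(recording); K <- length(recording$keypoint_names)
  D <- recording$dims
  df <- data.frame(frame = seq_len(Tn) - 1L)
  for (k in seq_len(K)) {
    for (d in seq_len(D)) {
      df[[paste0(recording$keypoint_names[k], "_", axis_names(D)[d])]] <-
        recording$coords[, k, d]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(fps = recording$fps, id = recording$id,
               keypoint_names = recording$keypoint_names,
               individual_of = recording$individual_of)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
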