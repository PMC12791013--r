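#' Build an imputation model
#'
#' Constructs an untrained imputer with one of three sequence backbones,
#' all implemented natively (hand-derived gradients, BLAS-backed):
#' \describe{
#'   \item{`transformer`}{tokens are (frame, keypoint) pairs. Each token's
#'     coordinates (plus its binary gap-mask bit) go through one shared
#'     linear projection, summed with lookup-table embeddings of the time
#'     index, the keypoint identity and the mask bit; the mask thus enters
#'     both concatenated and embedded. Post-LN encoder layers with
#'     multi-head self-attention and a linear output head. Defaults: 4
#'     layers, model dimension 128 (feed-forward width equal to it), 8
#'     heads.}
#'   \item{`gru`}{bidirectional GRU over frames; each keypoint contributes
#'     (x, y[, z], missing) input channels. Defaults: 3 layers, hidden 512,
#'     no dropout, linear output layer on the concatenated directions.}
#'   \item{`tcn`}{temporal convolutional network: 4 residual blocks of two
#'     causal dilated convolutions (kernel 3) with ReLU and dropout 0.2,
#'     dilations 1, 2, 4, 8, hidden 256.}
#' }
#' With `proba = TRUE` the model carries a probabilistic head predicting a
#' Gaussian mean and standard deviation per coordinate; the raw scale
#' output passes through a softplus with floor `1e-4` so the s.d. is
#' strictly positive. The per-sample mean predicted s.d. over masked cells
#' is the "estimated error" used to filter imputations.
#'
#' @param backbone `"transformer"`, `"gru"` or `"tcn"`.
#' @param K,D,L data shape: keypoints, coordinate dimensions (2 or 3),
#'   sample length in frames.
#' @param proba attach the probabilistic (Gaussian) head.
#' @param model_dim,n_layers,n_heads,dff transformer size parameters.
#' @param hidden hidden size (gru/tcn).
#' @param n_blocks,kernel tcn residual blocks and kernel size.
#' @param dropout tcn dropout rate.
#' @param heading,heading_pair view-invariant-rotation settings stored with
#'   the model and applied to every sample it sees (see
#'   [view_invariant_rotate()]). Configuring a body-intrinsic pair (e.g.
#'   tail to head) is strongly recommended: without one the heading sign
#'   depends on the world orientation, and recordings in which the animal
#'   persistently faces the "other" way are canonicalized inconsistently
#'   with training.
#' @param seed initialization seed.
#' @return object of class `skel_imputer`.
#' @export
build_model <- function(backbone = c("transformer", "gru", "tcn"), K, D, L = 60,
                        proba = FALSE, model_dim = 128, n_layers = NULL,
                        n_heads = 8, dff = NULL, hidden = NULL, n_blocks = 4,
                        kernel = 3, dropout = NULL,
                        heading = c("principal_axis", "pair"),
                        heading_pair = NULL, seed = 1) {
  backbone <- match.arg(backbone)
  heading <- match.arg(heading)
  if (!D %in% c(2, 3)) stop_config("D must be 2 or 3")
  cfg <- switch(backbone,
    transformer = list(L = as.integer(L), K = as.integer(K), D = as.integer(D),
                       model_dim = as.integer(model_dim),
                       n_heads = as.integer(n_heads),
                       n_layers = as.integer(n_layers %||% 4),
                       dff = as.integer(dff %||% model_dim), proba = proba),
    gru = list(L = as.integer(L), K = as.integer(K), D = as.integer(D),
               hidden = as.integer(hidden %||% 512),
               n_layers = as.integer(n_layers %||% 3), proba = proba),
    tcn = list(L = as.integer(L), K = as.integer(K), D = as.integer(D),
               hidden = as.integer(hidden %||% 256),
               n_blocks = as.integer(n_blocks), kernel = as.integer(kernel),
               dropout = dropout %||% 0.2, proba = proba))
  layout <- switch(backbone,
    transformer = cpp_tf_layout(cfg),
    gru = cpp_gru_layout(cfg),
    tcn = cpp_tcn_layout(cfg))
  theta <- init_params(layout, seed)
  structure(list(backbone = backbone, config = cfg, layout = layout,
                 theta = theta, seed = seed, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_,
                 train_config = NULL, n_missing_trained = NA,
                 preprocess = list(heading = heading, pair = heading_pair)),
            class = "skel_imputer")
}

# parameter initialization from a backbone layout: uniform(+-1/sqrt(fan))
# for linear weights and biases, small normal for embedding tables, ones /
# zeros for layer-norm gain / shift
init_params <- function(layout, seed) {
  with_seed(seed, {
    unlist(lapply(seq_len(nrow(layout)), function(i) {
      n <- layout$rows[i] * layout$cols[i]
      switch(as.character(layout$kind[i]),
        linear = ,
        bias = stats::runif(n, -1, 1) / sqrt(layout$fan[i]),
        embed = stats::rnorm(n, 0, 0.1),
        ln_g = rep(1, n),
        ln_b = rep(0, n),
        stop("unknown parameter kind"))
    }))
  })
}

#' @export
print.skel_imputer <- function(x, ...) {
  cat(sprintf("<skel_imputer %s%s: K=%d D=%d L=%d, %s parameters, %s>\n",
              x$backbone, if (x$config$proba) "-proba" else "",
              x$config$K, x$config$D, x$config$L,
              format(length(x$theta), big.mark = ","),
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
              else "untrained"))
  invisible(x)
}

#' @export
summary.skel_imputer <- function(object, ...) {
  print(object)
  cat("configuration:\n")
  utils::str(object$config, give.attr = FALSE)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("training: %d epochs, best val RMSE %.4g (epoch %d), final lr %.3g\n",
                nrow(h), min(h$val_rmse), object$best_epoch, h$lr[nrow(h)]))
  }
  invisible(object)
}

#' @export
coef.skel_imputer <- function(object, ...) object$theta

# ---- batch assembly -------------------------------------------------------
# transformer tokens are ordered keypoint-fastest: token i <-> (frame
# (i-1) %/% K + 1, keypoint (i-1) %% K + 1), matching the C++ side.

as_masked_list <- function(x) {
  if (inherits(x, "skel_masked")) list(x) else x
}

tf_assemble <- function(batch, cfg) {
  L <- cfg$L; K <- cfg$K; D <- cfg$D; B <- length(batch)
  n <- L * K
  inp <- array(0, c(n, D + 1, B))
  tgt <- array(0, c(n, D, B))
  msk <- matrix(0, n, B)
  for (b in seq_len(B)) {
    m <- batch[[b]]
    ib <- aperm(m$input, c(2, 1, 3)); dim(ib) <- c(n, D)
    inp[, 1:D, b] <- ib
    inp[, D + 1, b] <- as.numeric(t(m$gap_mask))
    tb <- aperm(m$target, c(2, 1, 3)); dim(tb) <- c(n, D)
    tgt[, , b] <- tb
    msk[, b] <- as.numeric(t(m$gap_mask))
  }
  list(input = inp, target = tgt, mask = msk)
}

tf_to_coords <- function(pred, cfg) {
  # n_tok x D x B -> list of L x K x D
  L <- cfg$L; K <- cfg$K; D <- cfg$D
  lapply(seq_len(dim(pred)[3]), function(b) {
    m <- pred[, , b]
    dim(m) <- c(K, L, D)
    aperm(m, c(2, 1, 3))
  })
}

seq_assemble <- function(batch, cfg) {
  # shared by gru and tcn: B x K*(D+1) x L input, B x K*D x L target,
  # B x K x L keypoint mask; channels are keypoint-major, coordinate-fastest
  L <- cfg$L; K <- cfg$K; D <- cfg$D; B <- length(batch)
  inp <- array(0, c(B, K * (D + 1), L))
  tgt <- array(0, c(B, K * D, L))
  msk <- array(0, c(B, K, L))
  for (b in seq_len(B)) {
    m <- batch[[b]]
    feat <- array(0, c(D + 1, K, L))
    feat[1:D, , ] <- aperm(m$input, c(3, 2, 1))
    feat[D + 1, , ] <- t(m$gap_mask)
    dim(feat) <- c(K * (D + 1), L)
    inp[b, , ] <- feat
    tg <- aperm(m$target, c(3, 2, 1))
    dim(tg) <- c(K * D, L)
    tgt[b, , ] <- tg
    msk[b, , ] <- t(m$gap_mask)
  }
  list(input = inp, target = tgt, mask = msk)
}

seq_to_coords <- function(pred, cfg) {
  # B x K*D x L -> list of L x K x D
  L <- cfg$L; K <- cfg$K; D <- cfg$D
  lapply(seq_len(dim(pred)[1]), function(b) {
    m <- pred[b, , ]
    dim(m) <- c(D, K, L)
    aperm(m, c(3, 2, 1))
  })
}

nn_assemble <- function(model, batch) {
  if (model$backbone == "transformer") tf_assemble(batch, model$config)
  else seq_assemble(batch, model$config)
}

nn_predict_raw <- function(model, asm) {
  switch(model$backbone,
    transformer = cpp_tf_predict(model$theta, asm$input, model$config),
    gru = cpp_gru_predict(model$theta, asm$input, model$config),
    tcn = cpp_tcn_predict(model$theta, asm$input, model$config))
}

nn_grad_raw <- function(model, asm, loss, dropout_seed = 0L, training = TRUE) {
  switch(model$backbone,
    transformer = cpp_tf_grad(model$theta, asm$input, asm$target, asm$mask,
                              model$config, loss),
    gru = cpp_gru_grad(model$theta, asm$input, asm$target, asm$mask,
                       model$config, loss),
    tcn = cpp_tcn_grad(model$theta, asm$input, asm$target, asm$mask,
                       model$config, loss, training, as.integer(dropout_seed)))
}

to_coords <- function(model, raw_field) {
  if (model$backbone == "transformer") tf_to_coords(raw_field, model$config)
  else seq_to_coords(raw_field, model$config)
}

#' Impute masked samples with a model
#'
#' Runs the network in evaluation mode (deterministic: no dropout, no gap
#' resampling) on one or more masked samples. Predictions are in the same
#' (normalized) space as the inputs; use [inverse_transform()] with the
#' sample's transform to return to original units.
#'
#' @param object a `skel_imputer`.
#' @param masked a `skel_masked` or list of them.
#' @param batch_size samples per forward pass.
#' @param ... unused.
#' @return a `skel_prediction` (fields `mean`, and `std` for probabilistic
#'   models, both `L x K x D`), or a list of them when given a list.
#' @export
predict.skel_imputer <- function(object, masked, batch_size = 32, ...) {
  single <- inherits(masked, "skel_masked")
  masked <- as_masked_list(masked)
  out <- vector("list", length(masked))
  starts <- seq(1, length(masked), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, length(masked))
    asm <- nn_assemble(object, masked[idx])
    raw <- nn_predict_raw(object, asm)
    means <- to_coords(object, raw$mean)
    stds <- if (object$config$proba) to_coords(object, raw$std) else NULL
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- structure(
        list(mean = means[[j]], std = if (is.null(stds)) NULL else stds[[j]],
             gap_mask = masked[[idx[j]]]$gap_mask,
             transform = masked[[idx[j]]]$transform),
        class = "skel_prediction")
    }
  }
  if (single) out[[1]] else out
}

#' @export
print.skel_prediction <- function(x, ...) {
  cat(sprintf("<skel_prediction %d x %d x %d%s>\n", dim(x$mean)[1],
              dim(x$mean)[2], dim(x$mean)[3],
              if (is.null(x$std)) "" else ", with std"))
  invisible(x)
}

#' Extract a latent representation of a sample
#'
#' Pools the final encoder-layer activations (mean over tokens for the
#' transformer, mean over frames of the bidirectional hidden state for the
#' GRU) into one fixed-length vector per sample, usable for downstream
#' embedding or behavior classification. Not available for the TCN.
#'
#' @param model a trained or untrained `skel_imputer`.
#' @param masked a `skel_masked` or list of them.
#' @return numeric vector, or matrix (samples in columns) for a list.
#' @export
extract_latent <- function(model, masked) {
  if (model$backbone == "tcn") {
    stop("latent extraction is not supported for the tcn backbone")
  }
  single <- inherits(masked, "skel_masked")
  asm <- nn_assemble(model, as_masked_list(masked))
  raw <- nn_predict_raw(model, asm)
  if (single) drop(raw$latent[, 1]) else raw$latent
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the configuration, the
#' flat parameter vector, the preprocessing settings and the training
#' history, so an imputation run is fully reproducible from it.
#' @param model a `skel_imputer`.
#' @param path file path.
#' @export
save_imputer <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_imputer
#' @export
load_imputer <- function(path) {
  structure(readRDS(path), class = "skel_imputer")
}
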