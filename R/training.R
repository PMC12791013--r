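#' Masked L1 loss
#'
#' Mean absolute deviation over masked coordinates only: positions and
#' keypoints outside the introduced gap contribute nothing, so all
#' supervision comes from reconstructing the hidden cells.
#'
#' @param pred `L x K x D` predicted means.
#' @param target `L x K x D` ground truth.
#' @param gap_mask `L x K` logical, `TRUE` on masked keypoint-frames.
#' @return non-negative scalar.
#' @export
masked_l1_loss <- function(pred, target, gap_mask) {
  cells <- masked_cells(gap_mask, dim(pred)[3])
  if (!any(cells)) stop("empty gap mask: no supervision signal")
  mean(abs(pred[cells] - target[cells]))
}

#' Gaussian negative log likelihood on masked cells
#'
#' Mean over masked coordinates of
#' `0.5 * log(2 * pi * sd^2) + (x - mean)^2 / (2 * sd^2)`. Minimised (for a
#' fixed residual) at `sd = |residual|`, which is what makes the predicted
#' s.d. an error estimate.
#'
#' @param mean,std,target `L x K x D` arrays; `std` strictly positive on
#'   masked cells.
#' @inheritParams masked_l1_loss
#' @export
gaussian_nll_loss <- function(mean, std, target, gap_mask) {
  cells <- masked_cells(gap_mask, dim(mean)[3])
  if (!any(cells)) stop("empty gap mask: no supervision signal")
  s <- std[cells]
  if (any(!is.finite(s)) || any(s <= 0)) stop("std must be positive on masked cells")
  r <- mean[cells] - target[cells]
  base::mean(0.5 * log(2 * pi * s^2) + r^2 / (2 * s^2))
}

masked_cells <- function(gap_mask, D) {
  array(rep(gap_mask, D), c(dim(gap_mask), D))
}

# position-level RMSE in whatever units the arrays are in (see metrics.R
# for the documented original-units entry point)
rmse_masked <- function(pred, target, gap_mask) {
  D <- dim(pred)[3]
  sq <- matrix(0, dim(pred)[1], dim(pred)[2])
  for (d in seq_len(D)) sq <- sq + (pred[, , d] - target[, , d])^2
  sqrt(mean(sq[gap_mask]))
}

scheduled_lr <- function(lr0, gamma, step, epoch0) {
  lr0 * gamma^(epoch0 %/% step)
}

best_epoch_from <- function(val_rmse) which.min(val_rmse)

#' Train an imputation model
#'
#' Self-supervised masked-modeling loop. Every epoch, each (complete,
#' preprocessed) training sample receives freshly sampled artificial gaps
#' drawn from the empirical missingness statistics -- gap insertion is a
#' form of data augmentation, so the network never sees the same masking
#' twice -- plus, optionally, a random keypoint switch. The masked L1 loss
#' (or the Gaussian NLL for probabilistic heads) is minimised with Adam
#' under a step learning-rate schedule (`lr * gamma^floor(epoch / step)`,
#' 0-based epochs). Validation gaps are frozen once at the start (seeded)
#' so checkpoint selection compares epochs on identical tasks; the
#' parameters from the epoch with the lowest validation RMSE (computed in
#' normalized space) are returned.
#'
#' Defaults follow the reference configuration: learning rate `1e-3`
#' (`1e-4` for the GRU, which is unstable at higher rates), scheduler decay
#' 0.95 every 500 epochs, batches of at most 32, switch probability 0.1.
#' Full-scale trainings run 1500 epochs; desk-scale experiments in the
#' package use far fewer (see the vignette).
#'
#' @param model an untrained (or warm) `skel_imputer`.
#' @param train_samples,val_samples lists of complete [skel_sample] in
#'   original coordinates; preprocessing (rotation + normalization) is
#'   applied internally per the model's `preprocess` settings.
#' @param gap_stats a `skel_gapstats` driving artificial gap sampling.
#' @param epochs number of epochs.
#' @param lr initial learning rate (backbone default when `NULL`).
#' @param scheduler_gamma,scheduler_step step-decay schedule.
#' @param batch_size at most 32 recommended.
#' @param switch_prob keypoint-switch augmentation probability.
#' @param n_missing gaps per sample: integer or vector (see [sample_gaps()]).
#' @param loss `"l1"` or `"nll"`; default `"nll"` for probabilistic models.
#' @param seed master seed; the run is deterministic given it.
#' @param clip_grad optional gradient-norm clip (off by default).
#' @param verbose print progress every 50 epochs.
#' @return the model with trained parameters (best epoch), `history`
#'   data frame (`epoch`, `lr`, `train_loss`, `val_rmse`) and `best_epoch`.
#' @export
train_imputer <- function(model, train_samples, val_samples, gap_stats,
                          epochs = 1500, lr = NULL, scheduler_gamma = 0.95,
                          scheduler_step = 500, batch_size = 32,
                          switch_prob = 0.1, n_missing = 1, loss = NULL,
                          seed = 0, clip_grad = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "skel_imputer"))
  if (length(train_samples) == 0 || length(val_samples) == 0) {
    stop_config("train and validation sample sets must be non-empty")
  }
  loss <- loss %||% (if (model$config$proba) "nll" else "l1")
  lr0 <- lr %||% (if (model$backbone == "gru") 1e-4 else 1e-3)
  prep <- function(s) preprocess_sample(s, model$preprocess$heading,
                                        model$preprocess$pair)
  if (any(!vapply(train_samples, is_complete, logical(1))) ||
      any(!vapply(val_samples, is_complete, logical(1)))) {
    stop("training requires complete samples (no native missing values)")
  }
  train_pp <- lapply(train_samples, prep)
  val_pp <- lapply(val_samples, prep)
  L <- model$config$L

  # frozen validation gaps: the model-selection criterion is stationary
  val_masked <- with_seed(derive_seed(seed, 1), {
    lapply(val_pp, function(s) apply_gaps(s, sample_gaps(gap_stats, L, n_missing)))
  })

  nt <- length(train_pp)
  n_par <- length(model$theta)
  m_adam <- numeric(n_par); v_adam <- numeric(n_par)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_adam <- 0
  hist_loss <- hist_rmse <- hist_lr <- numeric(epochs)
  best_rmse <- Inf; best_theta <- model$theta; best_epoch <- NA_integer_

  for (e in seq_len(epochs)) {
    lr_e <- scheduled_lr(lr0, scheduler_gamma, scheduler_step, e - 1L)
    ep <- with_seed(derive_seed(seed, 2, e), {
      ord <- sample.int(nt)
      masked <- lapply(train_pp[ord], function(s) {
        m <- apply_gaps(s, sample_gaps(gap_stats, L, n_missing))
        if (switch_prob > 0) m <- apply_switch(m, switch_prob)
        m
      })
      masked
    })
    tot_loss <- 0; nb <- 0
    for (s0 in seq(1, nt, by = batch_size)) {
      idx <- s0:min(s0 + batch_size - 1, nt)
      asm <- nn_assemble(model, ep[idx])
      g <- nn_grad_raw(model, asm, loss,
                       dropout_seed = derive_seed(seed, 3, e, s0))
      if (!is.finite(g$loss)) {
        stop(sprintf("training diverged: non-finite loss at epoch %d (lr %.3g)", e, lr_e))
      }
      grad <- g$grad
      if (!is.null(clip_grad)) {
        nrm <- sqrt(sum(grad^2))
        if (nrm > clip_grad) grad <- grad * (clip_grad / nrm)
      }
      t_adam <- t_adam + 1
      m_adam <- beta1 * m_adam + (1 - beta1) * grad
      v_adam <- beta2 * v_adam + (1 - beta2) * grad^2
      mhat <- m_adam / (1 - beta1^t_adam)
      vhat <- v_adam / (1 - beta2^t_adam)
      model$theta <- model$theta - lr_e * mhat / (sqrt(vhat) + eps)
      tot_loss <- tot_loss + g$loss * length(idx)
      nb <- nb + length(idx)
    }
    val_rmse <- eval_val_rmse(model, val_masked, batch_size)
    hist_loss[e] <- tot_loss / nb
    hist_rmse[e] <- val_rmse
    hist_lr[e] <- lr_e
    if (val_rmse < best_rmse) {
      best_rmse <- val_rmse; best_theta <- model$theta; best_epoch <- e
    }
    if (verbose && (e %% 50 == 0 || e == 1)) {
      message(sprintf("epoch %4d  loss %.5f  val RMSE %.5f  lr %.2g",
                      e, hist_loss[e], val_rmse, lr_e))
    }
  }
  model$theta <- best_theta
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$history <- data.frame(epoch = seq_len(epochs), lr = hist_lr,
                              train_loss = hist_loss, val_rmse = hist_rmse)
  model$n_missing_trained <- max(n_missing)
  model$train_config <- list(epochs = epochs, lr = lr0,
                             scheduler_gamma = scheduler_gamma,
                             scheduler_step = scheduler_step,
                             batch_size = batch_size,
                             switch_prob = switch_prob, n_missing = n_missing,
                             loss = loss, seed = seed)
  model
}

# pooled position-level RMSE over a fixed masked validation set
eval_val_rmse <- function(model, val_masked, batch_size = 32) {
  sq_sum <- 0; n_pos <- 0
  for (s0 in seq(1, length(val_masked), by = batch_size)) {
    idx <- s0:min(s0 + batch_size - 1, length(val_masked))
    asm <- nn_assemble(model, val_masked[idx])
    raw <- nn_predict_raw(model, asm)
    means <- to_coords(model, raw$mean)
    for (j in seq_along(idx)) {
      mm <- val_masked[[idx[j]]]
      D <- mm$dims
      sq <- matrix(0, mm$length, length(mm$keypoint_names))
      for (d in seq_len(D)) sq <- sq + (means[[j]][, , d] - mm$target[, , d])^2
      sq_sum <- sq_sum + sum(sq[mm$gap_mask])
      n_pos <- n_pos + sum(mm$gap_mask)
    }
  }
  sqrt(sq_sum / n_pos)
}

#' @export
plot.skel_imputer <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "train loss",
       main = paste(x$backbone, "training"), ...)
  plot(h$epoch, h$val_rmse, type = "l", xlab = "epoch",
       ylab = "validation RMSE (normalized)", main = "model selection", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
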