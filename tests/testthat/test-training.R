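const_velocity_samples <- function(n, L = 20, K = 3, D = 2) {
  lapply(seq_len(n), function(i) {
    with_seed(1000 + i, {
      co <- array(0, c(L, K, D))
      v <- rnorm(D)
      x0 <- rnorm(D, sd = 5)
      for (k in seq_len(K)) {
        off <- rnorm(D, sd = 3)
        for (d in seq_len(D)) co[, k, d] <- x0[d] + off[d] + v[d] * (0:(L - 1))
      }
      skelimpute:::new_sample(co, matrix(FALSE, L, K), paste0("cv", i), 0L, 60,
                              paste0("kp", seq_len(K)))
    })
  })
}

test_that("masked L1 loss matches its closed forms and a brute-force loop", {
  s <- preprocess_sample(rand_sample(L = 8, K = 3, D = 3, seed = 1))
  m <- apply_gaps(s, list(list(keypoint = 2, start = 3, length = 2)))
  expect_equal(masked_l1_loss(m$target, m$target, m$gap_mask), 0)
  pred <- m$target
  pred[4, 2, ] <- pred[4, 2, ] + c(1, 1, 1)
  gm1 <- matrix(FALSE, 8, 3); gm1[4, 2] <- TRUE
  expect_equal(masked_l1_loss(pred, m$target, gm1), 1.0)
  # random case vs explicit loop
  pred <- m$target + array(rnorm(length(m$target)), dim(m$target))
  acc <- 0; n <- 0
  for (t in 1:8) for (k in 1:3) if (m$gap_mask[t, k]) for (d in 1:3) {
    acc <- acc + abs(pred[t, k, d] - m$target[t, k, d]); n <- n + 1
  }
  expect_equal(masked_l1_loss(pred, m$target, m$gap_mask), acc / n,
               tolerance = 1e-12)
  expect_error(masked_l1_loss(pred, m$target, matrix(FALSE, 8, 3)), "empty")
})

test_that("gaussian NLL matches the closed form and is minimized at sd = |residual|", {
  L <- 4; K <- 2; D <- 3
  gm <- matrix(FALSE, L, K); gm[2, 1] <- TRUE
  tgt <- array(0, c(L, K, D))
  std1 <- array(1, c(L, K, D))
  expect_equal(gaussian_nll_loss(tgt, std1, tgt, gm), 0.5 * log(2 * pi),
               tolerance = 1e-12)   # ~0.91894 per cell
  # doubling sigma at zero residual adds log 2
  expect_equal(gaussian_nll_loss(tgt, std1 * 2, tgt, gm) -
                 gaussian_nll_loss(tgt, std1, tgt, gm), log(2), tolerance = 1e-12)
  # calculus oracle: for fixed residual r the optimum in sigma is |r|
  pred <- tgt; pred[2, 1, ] <- 0.7
  f <- function(s) gaussian_nll_loss(pred, array(s, dim(tgt)), tgt, gm)
  opt <- stats::optimize(f, c(0.05, 5))$minimum
  expect_equal(opt, 0.7, tolerance = 1e-4)
  eps <- 1e-4
  expect_gt(f(0.7 + eps), f(0.7)); expect_gt(f(0.7 - eps), f(0.7))
  bad <- std1; bad[2, 1, 1] <- 0
  expect_error(gaussian_nll_loss(pred, bad, tgt, gm), "positive")
})

test_that("the learning-rate schedule is lr * gamma^floor(epoch/step)", {
  lr <- skelimpute:::scheduled_lr
  e <- 0:1999
  expect_equal(lr(1e-3, 0.95, 500, e), 1e-3 * 0.95^(e %/% 500))
  expect_equal(lr(1e-4, 0.95, 500, 499), 1e-4)
  expect_equal(lr(1e-4, 0.95, 500, 500), 1e-4 * 0.95)
})

test_that("checkpoint selection picks the epoch with minimal validation RMSE", {
  expect_equal(skelimpute:::best_epoch_from(c(5, 3, 4)), 2)  # 1-based
  expect_equal(skelimpute:::best_epoch_from(c(2, 2, 1, 1)), 3)
})

test_that("loss ignores perturbations of unmasked target cells", {
  m <- tiny_cfg("gru")
  mk <- tiny_masked(seed = 2)
  asm <- skelimpute:::nn_assemble(m, list(mk))
  base <- skelimpute:::nn_grad_raw(m, asm, "l1")
  mk2 <- mk
  mk2$target[1, 2, ] <- mk2$target[1, 2, ] + 100  # unmasked cell
  asm2 <- skelimpute:::nn_assemble(m, list(mk2))
  pert <- skelimpute:::nn_grad_raw(m, asm2, "l1")
  expect_identical(pert$loss, base$loss)
  expect_identical(pert$grad, base$grad)
})

test_that("a training run learns constant-velocity motion and is reproducible", {
  tr <- const_velocity_samples(96)
  va <- const_velocity_samples(12)
  gs <- known_gap_stats(K = 3, p = rep(1, 3) / 3,
                        lens = list(c(3, 6), c(3, 6), c(3, 6)))
  m0 <- build_model("gru", K = 3, D = 2, L = 20, hidden = 32, n_layers = 1, seed = 1)
  m1 <- train_imputer(m0, tr, va, gs, epochs = 400, lr = 3e-3,
                      scheduler_step = 150, scheduler_gamma = 0.5,
                      batch_size = 16, switch_prob = 0, seed = 3)
  h <- m1$history
  expect_equal(nrow(h), 400)
  expect_lt(h$train_loss[400], 0.1 * h$train_loss[1])
  expect_equal(m1$best_epoch, which.min(h$val_rmse))
  expect_true(all(h$val_rmse[m1$best_epoch] <= h$val_rmse))
  # trained model beats its untrained self on a fixed evaluation set
  eval_set <- with_seed(9, lapply(const_velocity_samples(8), function(s) {
    apply_gaps(preprocess_sample(s), sample_gaps(gs, 20))
  }))
  err <- function(mm) {
    preds <- predict(mm, eval_set)
    mean(vapply(seq_along(preds), function(i) {
      rmse(preds[[i]]$mean, eval_set[[i]]$target, eval_set[[i]]$gap_mask)
    }, numeric(1)))
  }
  expect_lt(err(m1), 0.5 * err(m0))
  # determinism: same master seed, same history
  m2 <- train_imputer(m0, tr[1:16], va, gs, epochs = 5, batch_size = 8,
                      switch_prob = 0.1, seed = 3)
  m3 <- train_imputer(m0, tr[1:16], va, gs, epochs = 5, batch_size = 8,
                      switch_prob = 0.1, seed = 3)
  expect_identical(m2$history, m3$history)
  expect_identical(m2$theta, m3$theta)
})

test_that("training rejects incomplete samples and empty sets", {
  tr <- const_velocity_samples(4)
  gs <- known_gap_stats(K = 3)
  m <- build_model("gru", K = 3, D = 2, L = 20, hidden = 8, n_layers = 1)
  expect_error(train_imputer(m, list(), tr, gs), "non-empty")
  bad <- tr
  bad[[1]]$missing[2, 1] <- TRUE
  expect_error(train_imputer(m, bad, tr, gs, epochs = 1), "complete")
})
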