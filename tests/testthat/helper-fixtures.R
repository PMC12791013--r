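# fixtures are generated in code; nothing is read from disk

# smooth complete sample: correlated random-walk body + per-keypoint offsets
rand_sample <- function(L = 60, K = 4, D = 3, seed = 1, scale = 10) {
  with_seed(seed, {
    center <- apply(matrix(rnorm(L * D, sd = scale / 10), L, D), 2, cumsum)
    co <- array(0, c(L, K, D))
    for (k in seq_len(K)) {
      off <- rnorm(D, sd = scale)
      for (d in seq_len(D)) co[, k, d] <- center[, d] + off[d] + rnorm(L, sd = 0.1)
    }
    skelimpute:::new_sample(co, matrix(FALSE, L, K), "fixture", 0L, 60,
                            paste0("kp", seq_len(K)))
  })
}

rand_recording <- function(T = 200, K = 4, D = 3, seed = 1) {
  with_seed(seed, {
    co <- array(0, c(T, K, D))
    for (k in seq_len(K)) {
      for (d in seq_len(D)) co[, k, d] <- cumsum(rnorm(T)) + rnorm(1, sd = 20)
    }
    skel_recording(co, fps = 60, id = paste0("rand", seed))
  })
}

with_seed <- skelimpute:::with_seed

expect_arrays_equal <- function(a, b, tol = 1e-9) {
  expect_lte(max(abs(a - b), na.rm = TRUE), tol)
}

# gap stats with fully known distributions, for sampler tests
known_gap_stats <- function(K = 3, p = c(0.5, 0.3, 0.2),
                            lens = list(c(2, 5, 9), c(3, 7), c(4))) {
  pmfs <- lapply(lens, function(l) stats::setNames(rep(1 / length(l), length(l)), l))
  names(pmfs) <- paste0("kp", seq_len(K))
  structure(list(p_keypoint = stats::setNames(p, names(pmfs)),
                 gap_length_pmf = pmfs,
                 intergap_pmf = stats::setNames(rep(1 / 20, 20), 1:20),
                 source_frame_count = 0L, keypoint_names = names(pmfs)),
            class = "skel_gapstats")
}

tiny_cfg <- function(backbone, proba = FALSE) {
  switch(backbone,
    transformer = build_model("transformer", K = 2, D = 2, L = 6, proba = proba,
                              model_dim = 8, n_layers = 2, n_heads = 2, seed = 1),
    gru = build_model("gru", K = 2, D = 2, L = 6, proba = proba, hidden = 5,
                      n_layers = 2, seed = 1),
    tcn = build_model("tcn", K = 2, D = 2, L = 6, proba = proba, hidden = 6,
                      n_blocks = 2, dropout = 0, seed = 1))
}

tiny_masked <- function(seed = 1, L = 6, K = 2, D = 2) {
  s <- preprocess_sample(rand_sample(L = L, K = K, D = D, seed = seed))
  apply_gaps(s, list(list(keypoint = 1, start = 2, length = 3)))
}


# independent run-length oracle shared by gap-model and synthetic tests
rle_oracle <- function(mask) {
  events <- list()
  for (k in seq_len(ncol(mask))) {
    col <- mask[, k]
    t <- 1
    while (t <= length(col)) {
      if (col[t]) {
        s <- t
        while (t <= length(col) && col[t]) t <- t + 1
        events[[length(events) + 1]] <- c(k = k, len = t - s)
      } else t <- t + 1
    }
  }
  do.call(rbind, events)
}

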