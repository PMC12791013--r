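# Desk-scale trained models are expensive; they are trained once per test
# run and shared across test blocks through this cache. Sizes are the
# package's desk-scale study conditions (see the methods vignette).

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .model_cache)) {
    assign(key, builder(), envir = .model_cache)
  }
  get(key, envir = .model_cache)
}

# oscillatory mouse-like fixture: train/val/test complete samples plus
# held-out long-gap evaluation tasks
mouse8_study <- function() {
  cached("mouse8_study", function() {
    sp <- motion_spec("mouse8")
    recs <- lapply(1:3, function(i) simulate_recording(sp, T = 1560, seed = 100 + i))
    samples <- unlist(lapply(recs, extract_samples, length = 60, stride = 30,
                             complete_only = TRUE), recursive = FALSE)
    test_rec <- simulate_recording(sp, T = 1560, seed = 200)
    test_samples <- extract_samples(test_rec, 60, 60, complete_only = TRUE)
    list(spec = sp, recs = recs,
         train = samples[1:96], val = samples[97:120],
         train_gru = samples[1:120],
         test = test_samples,
         gap_stats = estimate_gap_stats(recs[[1]]))
  })
}

# frozen long-gap (>= 30 frames) evaluation tasks on the held-out samples
mouse8_long_gap_tasks <- function() {
  cached("mouse8_long_gaps", function() {
    st <- mouse8_study()
    with_seed(42, {
      lapply(st$test, function(s) {
        len <- sample(30:58, 1)
        start <- sample.int(59 - len, 1) + 1
        k <- sample.int(8, 1)
        list(sample = s, gap = list(keypoint = k, start = start, length = len))
      })
    })
  })
}

acceptance_transformer <- function() {
  cached("acc_transformer", function() {
    st <- mouse8_study()
    m <- build_model("transformer", K = 8, D = 3, L = 60, proba = TRUE,
                     model_dim = 32, n_layers = 2, n_heads = 2,
                     heading_pair = c("left_hip", "left_back"), seed = 1)
    train_imputer(m, st$train, st$val, st$gap_stats, epochs = 200,
                  batch_size = 32, switch_prob = 0.1, n_missing = 1, seed = 5)
  })
}

acceptance_gru <- function() {
  cached("acc_gru", function() {
    st <- mouse8_study()
    m <- build_model("gru", K = 8, D = 3, L = 60, proba = FALSE, hidden = 64,
                     n_layers = 2, heading_pair = c("left_hip", "left_back"),
                     seed = 2)
    train_imputer(m, st$train_gru, st$val, st$gap_stats, epochs = 200,
                  batch_size = 32, switch_prob = 0.1, n_missing = 1, seed = 6)
  })
}

# heteroscedastic fixture: per-60-frame-block noise level drawn from
# {0.01, 0.05, 0.1} normalized units (~ {0.5, 2.5, 5} mm at body scale)
hetero_study <- function() {
  cached("hetero_study", function() {
    sp <- motion_spec("mouse8", noise_levels = c(0.5, 2.5, 5), noise_block = 60)
    train_recs <- lapply(1:3, function(i) simulate_recording(sp, T = 1800, seed = 300 + i))
    test_recs <- lapply(1:2, function(i) simulate_recording(sp, T = 6600, seed = 400 + i))
    train <- unlist(lapply(train_recs, extract_samples, length = 60, stride = 60,
                           complete_only = TRUE), recursive = FALSE)
    test <- unlist(lapply(test_recs, extract_samples, length = 60, stride = 60,
                          complete_only = TRUE), recursive = FALSE)
    list(train = train[1:72], val = train[73:90], test = test,
         gap_stats = estimate_gap_stats(train_recs[[1]]))
  })
}

acceptance_proba <- function() {
  cached("acc_proba", function() {
    st <- hetero_study()
    m <- build_model("gru", K = 8, D = 3, L = 60, proba = TRUE, hidden = 64,
                     n_layers = 2, heading_pair = c("left_hip", "left_back"),
                     seed = 3)
    train_imputer(m, st$train, st$val, st$gap_stats, epochs = 150,
                  batch_size = 32, switch_prob = 0, n_missing = 1, seed = 7)
  })
}

# switch-robustness twins: identical except for the switch augmentation
switch_twins <- function() {
  cached("switch_twins", function() {
    st <- mouse8_study()
    build <- function(sw) {
      m <- build_model("gru", K = 8, D = 3, L = 60, proba = FALSE, hidden = 64,
                       n_layers = 2, heading_pair = c("left_hip", "left_back"),
                       seed = 4)
      # lr 1e-3 is stable on the synthetic fixture and trains the twins far
      # enough that switch robustness is expressed (the conservative 1e-4
      # GRU default guards against instability on real data)
      train_imputer(m, st$train, st$val, st$gap_stats, epochs = 150, lr = 1e-3,
                    batch_size = 32, switch_prob = sw, n_missing = 1,
                    scheduler_step = 50, seed = 8)
    }
    list(with_switch = build(0.1), without = build(0))
  })
}
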