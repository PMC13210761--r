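small_arch <- function(variant = "cnn_bilstm", n_channels = 12L) {
  architecture_config(variant, temporal_filters = 3L, spatial_filters = 4L,
                      bilstm_units = 4L, dropout = 0.5,
                      n_channels = n_channels)
}

test_that("analytic gradients match finite differences for every variant", {
  for (variant in c("cnn_bilstm", "cnn_only", "bilstm_only", "gru_only")) {
    set.seed(42)
    arch <- architecture_config(variant, temporal_filters = 3L,
                                spatial_filters = 4L, bilstm_units = 3L,
                                dropout = 0, n_channels = 4L)
    b <- 3L; t_ <- 12L; c_ <- 4L
    x <- array(rnorm(b * t_ * c_), c(b, t_, c_))
    y <- c(1L, 2L, 1L)
    params <- strokesense:::init_params(arch, c_)
    bn <- strokesense:::init_bn_state(arch)
    loss_fn <- function(p) {
      fwd <- strokesense:::net_forward(p, x, arch, bn, train = TRUE)
      strokesense:::softmax_ce(fwd$logits, y)$loss
    }
    fwd <- strokesense:::net_forward(params, x, arch, bn, train = TRUE)
    ce <- strokesense:::softmax_ce(fwd$logits, y)
    g <- strokesense:::net_backward(params, ce$dlogits, arch, fwd$cache)
    for (nm in names(g)) {
      pv <- params[[nm]]
      for (k in sample(seq_along(pv), min(4L, length(pv)))) {
        eps <- 1e-5
        p1 <- params; p1[[nm]][k] <- p1[[nm]][k] + eps
        p2 <- params; p2[[nm]][k] <- p2[[nm]][k] - eps
        num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
        ana <- g[[nm]][k]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-2,
                  label = paste(variant, nm))
      }
    }
  }
})

test_that("forward pass respects the architecture contracts", {
  set.seed(1)
  x <- array(rnorm(2 * 100 * 12), c(2, 100, 12))
  arch <- small_arch()
  params <- strokesense:::init_params(arch, 12L)
  fwd <- strokesense:::net_forward(params, x, arch,
                                   strokesense:::init_bn_state(arch))
  sm <- strokesense:::softmax_ce(fwd$logits, c(1L, 1L))
  expect_equal(rowSums(sm$probs), c(1, 1), tolerance = 1e-9)
  # spatial fusion collapses the 12-channel axis: sequence is length 50
  expect_equal(nrow(fwd$cache$seq_mat), 2L * 50L)
  # penultimate width = 2 x recurrent units
  expect_equal(ncol(fwd$emb), 2L * arch$bilstm_units)

  # ablation contract: the pure recurrent variants carry no conv weights
  gru_p <- strokesense:::init_params(small_arch("gru_only"), 12L)
  expect_false(any(grepl("^wc", names(gru_p))))
  cnn_p <- strokesense:::init_params(small_arch("cnn_only"), 12L)
  expect_false(any(grepl("^wx", names(cnn_p))))
})

test_that("learning-rate schedule steps by gamma every 15 epochs", {
  tc <- train_config()
  expect_equal(lr_at_epoch(tc, 1), 1e-3)
  expect_equal(lr_at_epoch(tc, 15), 1e-3)
  expect_equal(lr_at_epoch(tc, 16), 2e-4)
  expect_equal(lr_at_epoch(tc, 30), 2e-4)
  expect_equal(lr_at_epoch(tc, 31), 4e-5)
})

test_that("augmentation leaves held-out windows bit-identical", {
  tensor <- toy_tensor(10)
  train_mask <- rep(c(TRUE, FALSE), 5)
  set.seed(77)
  aug <- augment(tensor, train_mask, augment_config())
  n_train <- sum(train_mask)
  expect_equal(dim(aug$windows)[1], 10L + n_train)  # 1 copy per train window
  # original block is bit-identical, train or not
  expect_identical(aug$windows[1:10, , , , drop = FALSE], tensor$windows)
  expect_false(any(aug$meta$augmented[1:10]))
  expect_true(all(aug$meta$augmented[11:15]))
  # augmented copies inherit their source labels
  expect_equal(aug$meta$skill[11:15],
               tensor$meta$skill[aug$meta$source_row[11:15]])
})

test_that("augmentation shift uses edge replication and moves the peak", {
  tensor <- toy_tensor(1)
  cfg <- augment_config(shift_max = 5L, jitter_sd_fraction = 0,
                        scale_range = c(1, 1))
  w <- tensor_window(tensor, 1)
  seen_shifts <- integer(0)
  for (seed in 1:12) {
    set.seed(seed)
    aug <- augment(tensor, TRUE, cfg)
    out <- matrix(aug$windows[2, , , 1], 100, 12)
    s <- 41L - which.max(magnitude(out[, 1:3]))
    # a shift of +s pulls the window content earlier: out[t] = w[t + s]
    idx <- pmin(pmax(1:100 + s, 1L), 100L)
    expect_equal(out, w[idx, ], ignore_attr = TRUE)
    seen_shifts <- c(seen_shifts, s)
  }
  expect_gt(length(unique(seen_shifts)), 1L)
  expect_true(all(abs(seen_shifts) <= 5L))
})

test_that("training is seed-reproducible and records history", {
  tensor <- simulate_windows(40, quiet_config(noise_sd = 0.5), seed = 3,
                             stroke_types = "forehand")
  tc <- train_config(epochs = 2L, batch_size = 16L, seed = 9L)
  m1 <- train_model(small_arch(), tensor, tensor$meta$skill, tc)
  m2 <- train_model(small_arch(), tensor, tensor$meta$skill, tc)
  expect_equal(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$history), 2L)
  expect_equal(m1$history$lr, c(1e-3, 1e-3))

  expect_error(train_model(small_arch(), tensor,
                           rep("elite", dim(tensor$windows)[1]), tc),
               class = "strokesense_value_error")
})

test_that("prediction contracts hold", {
  tensor <- simulate_windows(30, quiet_config(noise_sd = 0.5), seed = 4,
                             stroke_types = "forehand")
  tc <- train_config(epochs = 2L, batch_size = 16L, seed = 5L)
  m <- train_model(small_arch(), tensor, tensor$meta$skill, tc)

  p0 <- predict(m, assemble_tensor(list()))
  expect_equal(nrow(p0), 0L)

  dup <- assemble_tensor(list(tensor_window(tensor, 1),
                              tensor_window(tensor, 1),
                              tensor_window(tensor, 2)))
  pd <- predict(m, dup)
  expect_identical(pd[1, ], pd[2, ])
  expect_equal(pd$.prob_amateur + pd$.prob_elite, rep(1, 3), tolerance = 1e-6)

  e <- embed(m, dup)
  expect_equal(dim(e), c(3L, 2L * m$arch$bilstm_units))
  expect_identical(e[1, ], e[2, ])
  expect_identical(embed(m, dup), e)
})

test_that("every ablation variant learns, the hybrid best", {
  tensor <- simulate_windows(100, simulation_config(), seed = 31,
                             stroke_types = "forehand")
  n <- dim(tensor$windows)[1]
  set.seed(8)
  test_idx <- sample(n, 60)
  train_t <- assemble_tensor(lapply(setdiff(1:n, test_idx), tensor_window,
                                    tensor = tensor),
                             tensor$meta[setdiff(1:n, test_idx), ])
  test_t <- assemble_tensor(lapply(test_idx, tensor_window, tensor = tensor),
                            tensor$meta[test_idx, ])
  # raw-sequence recurrent variants converge slower on subtle amplitude
  # differences; each gets a budget it can meet at desk scale
  budgets <- list(cnn_bilstm = list(lr = 3e-3, floor = 0.90),
                  cnn_only = list(lr = 3e-3, floor = 0.80),
                  bilstm_only = list(lr = 3e-3, floor = 0.75),
                  gru_only = list(lr = 1e-2, floor = 0.70))
  acc <- numeric(0)
  for (variant in names(budgets)) {
    arch <- architecture_config(variant, temporal_filters = 4L,
                                spatial_filters = 8L, bilstm_units = 8L)
    tc <- train_config(lr = budgets[[variant]]$lr, epochs = 50L,
                       batch_size = 35L, seed = 21L)
    m <- train_model(arch, train_t, train_t$meta$skill, tc)
    acc[variant] <- mean(predict(m, test_t)$.pred_class == test_t$meta$skill)
    expect_gte(acc[variant], budgets[[variant]]$floor)
  }
  # spatial-temporal fusion dominates each single-mechanism ablation
  expect_true(all(acc["cnn_bilstm"] + 0.01 >= acc))
})
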