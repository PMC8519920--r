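# tiny architectures keep the gradient checks and training smoke tests fast
tiny_cnn_cfg <- function() {
  cnn_config(n_max = 12, channels = c(3, 4, 4, 4, 3), dense = c(8),
             dropout_rate = 0, conv2d_kernel = c(4, 5),
             conv1d_kernels = c(3, 3, 3, 1))
}

tiny_rnn_cfg <- function() {
  rnn_config(embedding_dim = 4, hidden_dim = 5, num_layers = 2, dense = c(6))
}

cnn_loss <- function(layers, X, y) {
  out <- duplexr:::nn_forward(layers, X, nrow(X), training = TRUE)$out[, 1]
  mean((out - y)^2)
}

rnn_loss <- function(parts, Tm, y, hidden) {
  out <- duplexr:::rnn_forward_batch(parts, Tm, hidden,
                                     training = TRUE)$out[, 1]
  mean((out - y)^2)
}

test_that("parameter counts match an independent sum over layer shapes", {
  cfg <- cnn_config(lite = TRUE)
  m <- build_model(cfg, rng_seed = 1)
  ch <- c(2, cfg$channels)
  w <- cfg$n_max - cfg$conv2d_kernel[2] + 1
  conv_p <- 4 * cfg$conv2d_kernel[2] * ch[1] * ch[2] + ch[2]
  for (i in seq_along(cfg$conv1d_kernels)) {
    conv_p <- conv_p + cfg$conv1d_kernels[i] * ch[i + 1] * ch[i + 2] + ch[i + 2]
    w <- w - cfg$conv1d_kernels[i] + 1
  }
  bn_p <- 2 * sum(cfg$channels)
  dims <- c(w * cfg$channels[length(cfg$channels)], cfg$dense, 1)
  dense_p <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  expect_equal(m$n_params, conv_p + bn_p + dense_p)

  rcfg <- rnn_config()
  r <- build_model(rcfg, rng_seed = 1)
  lstm_p <- 2 * (4 * rcfg$embedding_dim * rcfg$hidden_dim +
                 4 * rcfg$hidden_dim^2 + 4 * rcfg$hidden_dim)
  rdims <- c(2 * rcfg$hidden_dim, rcfg$dense, 1)
  rdense_p <- sum(rdims[-length(rdims)] * rdims[-1] + rdims[-1])
  expect_equal(r$n_params,
               length(TOKEN_VOCAB) * rcfg$embedding_dim + lstm_p + rdense_p)
})

test_that("default parameter budgets are ordered CNN > CNN_Lite > RNN", {
  n_cnn <- build_model(cnn_config(), 1)$n_params
  n_lite <- build_model(cnn_config(lite = TRUE), 1)$n_params
  n_rnn <- build_model(rnn_config(), 1)$n_params
  expect_gt(n_cnn, n_lite)
  expect_gt(n_lite, n_rnn)
  # near the intended budgets (guidance, wide bands)
  expect_true(n_cnn > 2e6 && n_cnn < 4e6)
  expect_true(n_lite > 3e5 && n_lite < 7e5)
  expect_true(n_rnn > 1.5e5 && n_rnn < 3.5e5)
})

test_that("convolutional backprop matches numeric gradients", {
  set.seed(51)
  model <- build_model(tiny_cnn_cfg(), rng_seed = 51)
  layers <- model$layers
  pr <- list(a = random_sequence(10, 6), b = random_sequence(11, 6))
  X <- encode_image_batch(pr$a, pr$b, n_max = 12)
  y <- runif(6)
  fw <- duplexr:::nn_forward(layers, X, nrow(X), training = TRUE)
  dout <- matrix(2 * (fw$out[, 1] - y) / length(y), ncol = 1)
  grads <- duplexr:::nn_backward(fw$layers, fw$caches, dout, nrow(X))$grads
  eps <- 1e-5
  for (li in seq_along(layers)) {
    if (length(layers[[li]]$par) == 0) next
    for (pn in names(layers[[li]]$par)) {
      picks <- sample(length(layers[[li]]$par[[pn]]),
                      min(4, length(layers[[li]]$par[[pn]])))
      for (k in picks) {
        lp <- layers; lm <- layers
        lp[[li]]$par[[pn]][k] <- lp[[li]]$par[[pn]][k] + eps
        lm[[li]]$par[[pn]][k] <- lm[[li]]$par[[pn]][k] - eps
        num <- (cnn_loss(lp, X, y) - cnn_loss(lm, X, y)) / (2 * eps)
        expect_equal(grads[[li]][[pn]][k], num, tolerance = 1e-4,
                     info = sprintf("layer %d (%s) param %s[%d]",
                                    li, layers[[li]]$type, pn, k))
      }
    }
  }
})

test_that("recurrent backprop matches numeric gradients", {
  set.seed(52)
  model <- build_model(tiny_rnn_cfg(), rng_seed = 52)
  parts <- model$parts
  hidden <- model$config$hidden_dim
  pr <- list(a = random_sequence(6, 4), b = c(random_sequence(4, 3), "AC"))
  Tm <- encode_token_batch(pr$a, pr$b)
  y <- runif(4)
  fw <- duplexr:::rnn_forward_batch(parts, Tm, hidden, training = TRUE)
  dout <- matrix(2 * (fw$out[, 1] - y) / length(y), ncol = 1)
  g <- duplexr:::rnn_backward_batch(parts, fw, dout, hidden)
  eps <- 1e-5
  num_grad <- function(mutate_fn) {
    (rnn_loss(mutate_fn(parts, eps), Tm, y, hidden) -
     rnn_loss(mutate_fn(parts, -eps), Tm, y, hidden)) / (2 * eps)
  }
  # embedding entries
  for (k in sample(length(parts$E), 4)) {
    num <- num_grad(function(p, d) { p$E[k] <- p$E[k] + d; p })
    expect_equal(g$E[k], num, tolerance = 1e-4)
  }
  # both directions, both layers, all three tensors
  for (l in 1:2) for (dr in c("fwd", "bwd")) for (nm in c("Wx", "Wh", "b")) {
    vals <- parts$dirs[[l]][[dr]][[nm]]
    for (k in sample(length(vals), 3)) {
      num <- num_grad(function(p, d) {
        p$dirs[[l]][[dr]][[nm]][k] <- p$dirs[[l]][[dr]][[nm]][k] + d
        p
      })
      expect_equal(g$dirs[[l]][[dr]][[nm]][k], num, tolerance = 1e-4,
                   info = sprintf("layer %d %s %s[%d]", l, dr, nm, k))
    }
  }
  # head
  hW <- g$head[[1]]$W
  for (k in sample(length(hW), 3)) {
    num <- num_grad(function(p, d) {
      p$head[[1]]$par$W[k] <- p$head[[1]]$par$W[k] + d
      p
    })
    expect_equal(hW[k], num, tolerance = 1e-4)
  }
})

test_that("gradient flows to every trainable tensor on one step", {
  set.seed(53)
  model <- build_model(tiny_cnn_cfg(), rng_seed = 53)
  pr <- list(a = random_sequence(10, 8), b = random_sequence(11, 8))
  X <- encode_image_batch(pr$a, pr$b, n_max = 12)
  y <- runif(8)
  fw <- duplexr:::nn_forward(model$layers, X, nrow(X), training = TRUE)
  dout <- matrix(2 * (fw$out[, 1] - y) / length(y), ncol = 1)
  grads <- duplexr:::nn_backward(fw$layers, fw$caches, dout, nrow(X))$grads
  for (li in seq_along(model$layers)) {
    for (pn in names(grads[[li]])) {
      expect_gt(max(abs(grads[[li]][[pn]])), 0,
                label = sprintf("grad norm of layer %d %s", li, pn))
    }
  }
  # recurrent model: every tensor receives gradient except the top layer's
  # forward-direction recurrent matrix, which the first-position readout
  # structurally zeroes (the forward state at the begin token has no
  # recurrent history)
  rmodel <- build_model(tiny_rnn_cfg(), rng_seed = 53)
  Tm <- encode_token_batch(random_sequence(6, 8), random_sequence(5, 8))
  fwr <- duplexr:::rnn_forward_batch(rmodel$parts, Tm, 5, training = TRUE)
  doutr <- matrix(2 * (fwr$out[, 1] - runif(8)) / 8, ncol = 1)
  gr <- duplexr:::rnn_backward_batch(rmodel$parts, fwr, doutr, 5)
  expect_gt(max(abs(gr$E)), 0)
  for (l in 1:2) for (dr in c("fwd", "bwd")) for (nm in c("Wx", "Wh", "b")) {
    norm <- max(abs(gr$dirs[[l]][[dr]][[nm]]))
    if (l == 2 && dr == "fwd" && nm == "Wh") {
      expect_equal(norm, 0)
    } else {
      expect_gt(norm, 0, label = sprintf("layer %d %s %s", l, dr, nm))
    }
  }
})

test_that("training reduces the loss and retains the best checkpoint", {
  ds <- shared_small_dataset()
  model <- build_model(cnn_config(lite = TRUE, channels = c(8, 12, 12, 12, 8),
                                  dense = c(64), dropout_rate = 0.1),
                       rng_seed = 2)
  trained <- train_model(model, ds, epochs = 5, batch_size = 128,
                         learning_rate = 3e-3, rng_seed = 7)
  expect_true(trained$trained)
  expect_equal(nrow(trained$history), 5L)
  expect_lt(trained$history$train_loss[5], trained$history$train_loss[1])
  expect_equal(min(trained$history$val_mse),
               trained$metadata$best_val_mse)
})

test_that("training is deterministic for a fixed seed", {
  ds <- shared_small_dataset()
  cfg <- cnn_config(lite = TRUE, channels = c(4, 6, 6, 6, 4), dense = c(16))
  m1 <- train_model(build_model(cfg, rng_seed = 3), ds, epochs = 2,
                    batch_size = 256, rng_seed = 5)
  m2 <- train_model(build_model(cfg, rng_seed = 3), ds, epochs = 2,
                    batch_size = 256, rng_seed = 5)
  expect_identical(m1$history$val_mse, m2$history$val_mse)
})

test_that("the recurrent model trains on the token encoding", {
  ds <- shared_small_dataset()
  small <- ds
  keep <- c(which(ds$records$split == "train")[1:400],
            which(ds$records$split == "validation")[1:80])
  small$records <- ds$records[keep, ]
  model <- build_model(rnn_config(embedding_dim = 8, hidden_dim = 12,
                                  dense = c(16)), rng_seed = 4)
  trained <- train_model(model, small, epochs = 3, batch_size = 100,
                         rng_seed = 6)
  expect_lt(trained$history$train_loss[3], trained$history$train_loss[1])
  p <- predict_yield(trained, small$records$seq_a[1:5],
                     small$records$seq_b[1:5])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("predictions are order-preserving and batch-size invariant", {
  ds <- shared_small_dataset()
  cfg <- cnn_config(lite = TRUE, channels = c(4, 6, 6, 6, 4), dense = c(16))
  m <- train_model(build_model(cfg, rng_seed = 3), ds, epochs = 1,
                   batch_size = 256, rng_seed = 5)
  te <- dataset_split(ds, "test")
  p1 <- predict_yield(m, te$seq_a, te$seq_b, batch_size = 1)
  p2 <- predict_yield(m, te$seq_a, te$seq_b, batch_size = 512)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict_yield(m, strrep("A", 30), "ACGT"), "n_max")
  expect_warning(predict_yield(build_model(cfg, 1), "ACGTACGT", "ACGTACGT"),
                 "untrained")
})

test_that("checkpoints round-trip through disk", {
  ds <- shared_small_dataset()
  cfg <- cnn_config(lite = TRUE, channels = c(4, 6, 6, 6, 4), dense = c(16))
  m <- train_model(build_model(cfg, rng_seed = 3), ds, epochs = 1,
                   batch_size = 256, rng_seed = 5)
  dir <- tempfile("ckpt")
  save_checkpoint(m, dir)
  expect_true(file.exists(file.path(dir, "weights.rds")))
  side <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(side$architecture, "cnn_lite")
  expect_equal(side$n_params, m$n_params)
  m2 <- load_checkpoint(dir)
  te <- dataset_split(ds, "test")[1:20, ]
  expect_identical(predict_yield(m, te$seq_a, te$seq_b),
                   predict_yield(m2, te$seq_a, te$seq_b))
  expect_error(load_checkpoint(tempfile()), "no checkpoint")
})
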