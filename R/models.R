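#' Convolutional regressor configuration
#'
#' The convolutional yield regressor starts with a single 2-D convolution
#' whose kernel spans the full nucleobase axis (height 4, width 9), followed
#' by 1-D convolutions of widths 9, 3, 3 and 1; every convolution is
#' followed by rectified-linear activation and batch normalisation, with
#' dropout interspersed, and fully-connected layers predict the single yield
#' value. The lite variant narrows the channels and dense widths.
#'
#' @param lite build the reduced-size variant.
#' @param n_max maximum sequence length (image width), default 26.
#' @param channels output channels of the five convolution stages.
#' @param dense hidden widths of the fully-connected head.
#' @param dropout_rate dropout rate after each block.
#' @param conv2d_kernel height/width of the first (2-D) kernel; height must
#'   be 4 (the full one-hot axis).
#' @param conv1d_kernels widths of the four 1-D stages.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(lite = FALSE, n_max = 26L,
                       channels = if (lite) c(32, 64, 64, 64, 32)
                                  else c(64, 128, 256, 256, 128),
                       dense = if (lite) c(1024, 256) else c(2048, 512),
                       dropout_rate = 0.2,
                       conv2d_kernel = c(4L, 9L),
                       conv1d_kernels = c(9L, 3L, 3L, 1L)) {
  if (conv2d_kernel[1] != 4L)
    stop("the first kernel must span the full nucleobase axis (height 4)")
  if (length(conv1d_kernels) != length(channels) - 1L)
    stop("need one channel width per convolution stage")
  w <- n_max - conv2d_kernel[2] + 1L
  for (k in conv1d_kernels) {
    w <- w - k + 1L
    if (w < 1L) stop("convolution stack consumes the whole width")
  }
  structure(list(lite = lite, n_max = as.integer(n_max),
                 channels = as.integer(channels),
                 dense = as.integer(dense),
                 dropout_rate = dropout_rate,
                 conv2d_kernel = as.integer(conv2d_kernel),
                 conv1d_kernels = as.integer(conv1d_kernels)),
            class = "cnn_config")
}

#' Recurrent regressor configuration
#'
#' A character-level bidirectional LSTM over the token encoding
#' `<b> a <s> b <s>`; the last layer's hidden state at the first position
#' (the begin token, where the backward direction has consumed the whole
#' pair) feeds a dense head that outputs the yield.
#'
#' @param embedding_dim token embedding width.
#' @param hidden_dim LSTM hidden width per direction.
#' @param num_layers stacked bidirectional layers.
#' @param dense hidden widths of the readout head.
#' @return an `rnn_config` list.
#' @export
rnn_config <- function(embedding_dim = 32L, hidden_dim = 128L,
                       num_layers = 1L, dense = c(320L)) {
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 dense = as.integer(dense),
                 bidirectional = TRUE),
            class = "rnn_config")
}

cnn_layers <- function(cfg) {
  layers <- list()
  in_ch <- 2L
  layers <- c(layers, list(
    layer_conv2d(cfg$n_max, cfg$conv2d_kernel[1], cfg$conv2d_kernel[2],
                 in_ch, cfg$channels[1]),
    layer_relu(), layer_bnorm(cfg$channels[1]),
    layer_dropout(cfg$dropout_rate)))
  w <- cfg$n_max - cfg$conv2d_kernel[2] + 1L
  for (i in seq_along(cfg$conv1d_kernels)) {
    layers <- c(layers, list(
      layer_conv1d(cfg$conv1d_kernels[i], cfg$channels[i], cfg$channels[i + 1]),
      layer_relu(), layer_bnorm(cfg$channels[i + 1]),
      layer_dropout(cfg$dropout_rate)))
    w <- w - cfg$conv1d_kernels[i] + 1L
  }
  layers <- c(layers, list(layer_flatten()))
  nin <- w * cfg$channels[length(cfg$channels)]
  for (d in cfg$dense) {
    layers <- c(layers, list(layer_dense(nin, d), layer_relu(),
                             layer_dropout(cfg$dropout_rate)))
    nin <- d
  }
  c(layers, list(layer_dense(nin, 1L, init = glorot), layer_sigmoid()))
}

rnn_parts <- function(cfg) {
  vocab <- length(TOKEN_VOCAB)
  E <- glorot(vocab, cfg$embedding_dim)
  dirs <- list()
  in_dim <- cfg$embedding_dim
  for (l in seq_len(cfg$num_layers)) {
    dirs[[l]] <- list(fwd = lstm_dir_init(in_dim, cfg$hidden_dim),
                      bwd = lstm_dir_init(in_dim, cfg$hidden_dim))
    in_dim <- 2L * cfg$hidden_dim
  }
  head <- list()
  nin <- 2L * cfg$hidden_dim
  for (d in cfg$dense) {
    head <- c(head, list(layer_dense(nin, d), layer_relu()))
    nin <- d
  }
  head <- c(head, list(layer_dense(nin, 1L, init = glorot), layer_sigmoid()))
  list(E = E, dirs = dirs, head = head)
}

rnn_param_count <- function(parts) {
  n <- length(parts$E)
  for (l in parts$dirs) {
    for (d in l) n <- n + length(d$Wx) + length(d$Wh) + length(d$b)
  }
  n + nn_param_count(parts$head)
}

#' Build an (untrained) yield predictor
#'
#' @param config a [cnn_config()] or [rnn_config()].
#' @param rng_seed seed for the weight initialisation.
#' @return a `trained_predictor` with `trained = FALSE`; the trainable
#'   parameter count is in `$n_params`.
#' @export
build_model <- function(config, rng_seed = 1L) {
  set.seed(rng_seed)
  if (inherits(config, "cnn_config")) {
    layers <- cnn_layers(config)
    arch <- if (config$lite) "cnn_lite" else "cnn"
    structure(list(architecture = arch, config = config, layers = layers,
                   n_params = nn_param_count(layers), trained = FALSE,
                   metadata = list(init_seed = rng_seed)),
              class = "trained_predictor")
  } else if (inherits(config, "rnn_config")) {
    parts <- rnn_parts(config)
    structure(list(architecture = "rnn", config = config, parts = parts,
                   n_params = rnn_param_count(parts), trained = FALSE,
                   metadata = list(init_seed = rng_seed)),
              class = "trained_predictor")
  } else stop("config must be a cnn_config or rnn_config")
}

#' @export
print.trained_predictor <- function(x, ...) {
  cat(sprintf("<trained_predictor> %s, %s parameters, %s\n", x$architecture,
              format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (x$trained)
    cat(sprintf("  epochs %d, best validation MSE %.5f (T %g C)\n",
                nrow(x$history), min(x$history$val_mse),
                x$metadata$reference_temperature %||% NA))
  invisible(x)
}

# --- forward/backward drivers ----------------------------------------------

cnn_predict_batch <- function(model, Xb, training = FALSE) {
  nn_forward(model$layers, Xb, nrow(Xb), training = training)
}

rnn_forward_batch <- function(parts, Tm, hidden, training = FALSE) {
  batch <- nrow(Tm)
  Tlen <- ncol(Tm)
  pad <- TOKEN_VOCAB[["<pad>"]]
  mask_f <- (Tm != pad) * 1
  Xf <- lapply(seq_len(Tlen), function(t) parts$E[Tm[, t], , drop = FALSE])
  layer_caches <- list()
  in_f <- Xf
  for (l in seq_along(parts$dirs)) {
    in_b <- rev(in_f)
    mask_b <- mask_f[, rev(seq_len(Tlen)), drop = FALSE]
    ff <- lstm_dir_forward(parts$dirs[[l]]$fwd, in_f, mask_f, hidden)
    bb <- lstm_dir_forward(parts$dirs[[l]]$bwd, in_b, mask_b, hidden)
    layer_caches[[l]] <- list(ff = ff, bb = bb, in_f = in_f, in_b = in_b)
    if (l < length(parts$dirs)) {
      # next layer consumes [fwd_h_p, bwd_h_p] at each position p
      in_f <- lapply(seq_len(Tlen), function(p)
        cbind(ff$hs[[p]], bb$hs[[Tlen + 1L - p]]))
    } else {
      readout <- cbind(ff$hs[[1L]], bb$hs[[Tlen]])
    }
  }
  hw <- nn_forward(parts$head, readout, batch, training = training)
  list(out = hw$out, head = hw, layer_caches = layer_caches,
       Tm = Tm, Tlen = Tlen, readout = readout)
}

rnn_backward_batch <- function(parts, fw, dout, hidden) {
  batch <- nrow(fw$Tm)
  Tlen <- fw$Tlen
  hb <- nn_backward(parts$head, fw$head$caches, dout, batch)
  dreadout <- hb$dX
  zero <- matrix(0, batch, hidden)
  nl <- length(parts$dirs)
  dir_grads <- vector("list", nl)
  # gradient w.r.t. each layer's per-position outputs, top-down
  dh_f <- rep(list(zero), Tlen)
  dh_b <- rep(list(zero), Tlen)
  dh_f[[1L]] <- dreadout[, seq_len(hidden), drop = FALSE]
  dh_b[[Tlen]] <- dreadout[, hidden + seq_len(hidden), drop = FALSE]
  dE <- parts$E * 0
  for (l in rev(seq_len(nl))) {
    cc <- fw$layer_caches[[l]]
    gf <- lstm_dir_backward(parts$dirs[[l]]$fwd, cc$in_f, cc$ff$caches,
                            dh_f, hidden)
    gb <- lstm_dir_backward(parts$dirs[[l]]$bwd, cc$in_b, cc$bb$caches,
                            dh_b, hidden)
    dir_grads[[l]] <- list(fwd = gf[c("Wx", "Wh", "b")],
                           bwd = gb[c("Wx", "Wh", "b")])
    # input gradient per position: fwd step p + bwd step (Tlen + 1 - p)
    dIn <- lapply(seq_len(Tlen), function(p)
      gf$dXs[[p]] + gb$dXs[[Tlen + 1L - p]])
    if (l > 1L) {
      dh_f <- lapply(dIn, function(m) m[, seq_len(hidden), drop = FALSE])
      dh_b <- lapply(rev(seq_len(Tlen)), function(p)
        dIn[[p]][, hidden + seq_len(hidden), drop = FALSE])
    } else {
      for (p in seq_len(Tlen)) {
        tok <- fw$Tm[, p]
        for (v in unique(tok)) {
          rows <- tok == v
          dE[v, ] <- dE[v, ] + colSums(dIn[[p]][rows, , drop = FALSE])
        }
      }
    }
  }
  list(head = hb$grads, dirs = dir_grads, E = dE)
}

# pack RNN parameters/gradients into pseudo-layers so Adam can be reused
rnn_as_layers <- function(parts) {
  layers <- list(list(type = "embed", par = list(E = parts$E)))
  for (l in parts$dirs) {
    layers <- c(layers, list(list(type = "lstm", par = list(
      Wx_f = l$fwd$Wx, Wh_f = l$fwd$Wh, b_f = l$fwd$b,
      Wx_b = l$bwd$Wx, Wh_b = l$bwd$Wh, b_b = l$bwd$b))))
  }
  c(layers, parts$head)
}

rnn_from_layers <- function(parts, layers) {
  parts$E <- layers[[1]]$par$E
  nl <- length(parts$dirs)
  for (l in seq_len(nl)) {
    p <- layers[[1L + l]]$par
    parts$dirs[[l]] <- list(fwd = list(Wx = p$Wx_f, Wh = p$Wh_f, b = p$b_f),
                            bwd = list(Wx = p$Wx_b, Wh = p$Wh_b, b = p$b_b))
  }
  parts$head <- layers[-seq_len(1L + nl)]
  parts
}

rnn_grads_as_layers <- function(g, n_head) {
  layers <- list(list(E = g$E))
  for (l in g$dirs) {
    layers <- c(layers, list(list(
      Wx_f = l$fwd$Wx, Wh_f = l$fwd$Wh, b_f = l$fwd$b,
      Wx_b = l$bwd$Wx, Wh_b = l$bwd$Wh, b_b = l$bwd$b)))
  }
  c(layers, g$head)
}

# --- training --------------------------------------------------------------

#' Train a yield regressor
#'
#' Minimises the mean squared error between predicted and ground-truth
#' yields at the dataset's reference temperature with Adam; the parameters
#' achieving the best validation MSE are retained. Deterministic for a fixed
#' seed under single-threaded numerics.
#'
#' @param model an untrained (or previously trained) `trained_predictor`.
#' @param ds a `hyb_dataset` with train/validation splits assigned.
#' @param epochs training epochs.
#' @param batch_size minibatch size; defaults to 512 for the convolutional
#'   models and 8192 for the recurrent model.
#' @param learning_rate base Adam learning rate.
#' @param lr_schedule `"cosine"` (default) anneals the learning rate from
#'   the base value to 5 percent of it across the epochs; `"constant"`
#'   keeps it fixed.
#' @param clip_norm global gradient-norm ceiling per step (stabilises the
#'   occasional exploding update); `Inf` disables clipping.
#' @param swa_from first epoch included in stochastic weight averaging:
#'   parameters of epochs `swa_from..epochs` are averaged, batch
#'   normalisation statistics are refreshed with one pass over the training
#'   data, and the averaged model replaces the best single epoch when its
#'   validation MSE is lower. `NULL` (default) disables averaging.
#' @param rng_seed seed controlling shuffling, dropout and initialisation of
#'   the optimiser.
#' @param verbose print one line per epoch.
#' @return the trained predictor with `$history` (epoch, train_loss,
#'   val_mse).
#' @export
train_model <- function(model, ds, epochs = 10L, batch_size = NULL,
                        learning_rate = 2e-3,
                        lr_schedule = c("cosine", "constant"),
                        clip_norm = 5, swa_from = NULL,
                        rng_seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(inherits(model, "trained_predictor"))
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  ycol <- paste0("yield_", ds$reference_temperature)
  y_tr <- tr[[ycol]]; y_va <- va[[ycol]]
  batch_size <- batch_size %||% if (model$architecture == "rnn") 8192L else 512L
  set.seed(derive_seed(rng_seed, "train"))
  is_cnn <- model$architecture %in% c("cnn", "cnn_lite")
  if (is_cnn) {
    X_tr <- encode_image_batch(tr$seq_a, tr$seq_b, model$config$n_max)
    X_va <- encode_image_batch(va$seq_a, va$seq_b, model$config$n_max)
    layers <- model$layers
    astate <- adam_init(layers)
  } else {
    T_tr <- encode_token_batch(tr$seq_a, tr$seq_b)
    T_va <- encode_token_batch(va$seq_a, va$seq_b)
    hidden <- model$config$hidden_dim
    parts <- model$parts
    pl <- rnn_as_layers(parts)
    astate <- adam_init(pl)
  }
  n <- length(y_tr)
  swa <- NULL; swa_k <- 0L
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mse = numeric())
  best <- list(val = Inf)
  for (ep in seq_len(epochs)) {
    lr_ep <- if (lr_schedule == "cosine") {
      learning_rate * (0.05 + 0.95 * 0.5 *
                         (1 + cos(pi * (ep - 1) / max(epochs - 1, 1))))
    } else learning_rate
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      yb <- y_tr[idx]
      step <- step + 1L
      if (is_cnn) {
        fw <- nn_forward(layers, X_tr[idx, , drop = FALSE], length(idx),
                         training = TRUE)
        layers <- fw$layers # batch-norm running stats
        dout <- matrix(2 * (fw$out[, 1] - yb) / length(yb), ncol = 1L)
        bw <- nn_backward(layers, fw$caches, dout, length(idx))
        gcl <- clip_grads(bw$grads, clip_norm)
        upd <- adam_step(layers, gcl, astate, lr_ep, step)
        layers <- upd$layers; astate <- upd$state
        losses <- c(losses, mean((fw$out[, 1] - yb)^2))
      } else {
        fw <- rnn_forward_batch(parts, T_tr[idx, , drop = FALSE], hidden,
                                training = TRUE)
        dout <- matrix(2 * (fw$out[, 1] - yb) / length(yb), ncol = 1L)
        g <- rnn_backward_batch(parts, fw, dout, hidden)
        pl <- rnn_as_layers(parts)
        gl <- clip_grads(rnn_grads_as_layers(g, length(parts$head)), clip_norm)
        upd <- adam_step(pl, gl, astate, lr_ep, step)
        parts <- rnn_from_layers(parts, upd$layers)
        astate <- upd$state
        losses <- c(losses, mean((fw$out[, 1] - yb)^2))
      }
    }
    if (!is.null(swa_from) && ep >= swa_from) {
      cur <- if (is_cnn) layers else rnn_as_layers(parts)
      if (is.null(swa)) {
        swa <- cur; swa_k <- 1L
      } else {
        swa_k <- swa_k + 1L
        for (li in seq_along(cur)) {
          for (pn in names(cur[[li]]$par)) {
            swa[[li]]$par[[pn]] <- swa[[li]]$par[[pn]] +
              (cur[[li]]$par[[pn]] - swa[[li]]$par[[pn]]) / swa_k
          }
        }
      }
    }
    # validation pass (inference mode)
    if (is_cnn) {
      model$layers <- layers
      pv <- predict_matrix_cnn(model, X_va)
    } else {
      model$parts <- parts
      pv <- predict_matrix_rnn(model, T_va)
    }
    val_mse <- mean((pv - y_va)^2)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_mse = val_mse))
    if (val_mse < best$val) {
      best <- list(val = val_mse,
                   layers = if (is_cnn) layers else NULL,
                   parts = if (!is_cnn) parts else NULL)
    }
    if (verbose)
      message(sprintf("epoch %d  train MSE %.5f  val MSE %.5f",
                      ep, mean(losses), val_mse))
  }
  if (!is.null(swa)) {
    if (is_cnn) {
      swa_model <- model
      swa_model$layers <- bn_refresh(swa, X_tr, batch_size)
      swa_val <- mean((predict_matrix_cnn(swa_model, X_va) - y_va)^2)
    } else {
      swa_model <- model
      swa_model$parts <- rnn_from_layers(parts, swa)
      swa_val <- mean((predict_matrix_rnn(swa_model, T_va) - y_va)^2)
    }
    if (swa_val < best$val) {
      best <- list(val = swa_val,
                   layers = if (is_cnn) swa_model$layers else NULL,
                   parts = if (!is_cnn) swa_model$parts else NULL)
      history$val_mse[nrow(history)] <- swa_val
    }
  }
  if (is_cnn) model$layers <- best$layers else model$parts <- best$parts
  model$trained <- TRUE
  model$history <- history
  model$metadata <- c(model$metadata,
                      list(train_seed = rng_seed, epochs = epochs,
                           batch_size = batch_size,
                           learning_rate = learning_rate,
                           reference_temperature = ds$reference_temperature,
                           n_train = n, best_val_mse = best$val))
  model
}

predict_matrix_cnn <- function(model, X, batch_size = 2048L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- nn_forward(model$layers, X[idx, , drop = FALSE],
                           length(idx), training = FALSE)$out[, 1]
  }
  out
}

predict_matrix_rnn <- function(model, Tm, batch_size = 2048L) {
  n <- nrow(Tm)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- rnn_forward_batch(model$parts, Tm[idx, , drop = FALSE],
                                  model$config$hidden_dim,
                                  training = FALSE)$out[, 1]
  }
  out
}

#' Predict hybridisation yields for sequence pairs
#'
#' Order-preserving and invariant to the batch size (inference uses the
#' batch-normalisation running statistics).
#'
#' @param model a trained `trained_predictor`.
#' @param a,b character vectors of DNA sequences (recycled pairwise).
#' @param batch_size prediction batch size.
#' @return numeric vector of predicted yields in `[0, 1]`.
#' @export
predict_yield <- function(model, a, b, batch_size = 2048L) {
  stopifnot(inherits(model, "trained_predictor"))
  if (!model$trained) warning("predicting with an untrained model")
  a <- dna(a); b <- dna(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (model$architecture %in% c("cnn", "cnn_lite")) {
    X <- encode_image_batch(a, b, model$config$n_max)
    predict_matrix_cnn(model, X, batch_size)
  } else {
    Tm <- encode_token_batch(a, b)
    predict_matrix_rnn(model, Tm, batch_size)
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint directory holds a weights blob (`weights.rds`) and a JSON
#' sidecar (`config.json`) with the architecture, configuration, vocabulary
#' and training metadata.
#'
#' @param model a `trained_predictor`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  sidecar <- list(architecture = model$architecture,
                  config = unclass(model$config),
                  n_params = model$n_params,
                  vocabulary = as.list(TOKEN_VOCAB),
                  metadata = model$metadata)
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  f <- file.path(dir, "weights.rds")
  if (!file.exists(f)) stop("no checkpoint at ", dir)
  readRDS(f)
}
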