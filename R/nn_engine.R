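# Minimal feed-forward network engine used by the convolutional yield
# regressors. Activations flow as dense matrices; convolution is matrix
# multiplication over gathered patches (im2col). Activations of 1-D conv
# stages use a block layout of shape (batch * width) x channels, rows
# grouped by position: rows (p-1)*batch + 1:batch hold position p.
#
# Each layer is a list(type, ...) with parameters in $par (named list of
# matrices/vectors); nn_forward / nn_backward implement the hand-derived
# forward and reverse passes; Adam drives the updates.

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
}

# column-wise (per-channel) broadcast helpers; equivalent to sweep() on
# MARGIN = 2 but without its aperm() copies, which dominate profile time
addcol <- function(A, v) A + rep(v, each = nrow(A))
mulcol <- function(A, v) A * rep(v, each = nrow(A))


layer_conv2d <- function(n_max, kh, kw, in_ch, out_ch, init = glorot) {
  # patch gather indices into the flattened 4 x n_max x in_ch input
  w_out <- n_max - kw + 1L
  idx <- matrix(0L, kh * kw * in_ch, w_out)
  for (p in seq_len(w_out)) {
    k <- 1L
    for (ch in seq_len(in_ch)) for (col in p:(p + kw - 1L)) for (row in 1:kh) {
      idx[k, p] <- ((ch - 1L) * n_max + (col - 1L)) * 4L + row
      k <- k + 1L
    }
  }
  list(type = "conv2d", idx = idx, w_out = w_out,
       par = list(W = init(kh * kw * in_ch, out_ch),
                  b = numeric(out_ch)))
}

layer_conv1d <- function(k, in_ch, out_ch, init = glorot) {
  list(type = "conv1d", k = k,
       par = list(W = init(k * in_ch, out_ch), b = numeric(out_ch)))
}

layer_bnorm <- function(ch) {
  list(type = "bnorm", eps = 1e-5, momentum = 0.9,
       par = list(gamma = rep(1, ch), beta = rep(0, ch)),
       run_mean = rep(0, ch), run_var = rep(1, ch))
}

layer_relu <- function() list(type = "relu", par = list())
layer_dropout <- function(rate) list(type = "dropout", rate = rate, par = list())
layer_flatten <- function() list(type = "flatten", par = list())
layer_dense <- function(nin, nout, init = glorot) {
  list(type = "dense", par = list(W = init(nin, nout), b = numeric(nout)))
}
layer_sigmoid <- function() list(type = "sigmoid", par = list())

# gather 1-D conv patches: A is (batch*w_in) x C, returns (batch*w_out) x (k*C)
conv1d_patches <- function(A, k, batch) {
  w_in <- nrow(A) / batch
  w_out <- w_in - k + 1L
  cols <- lapply(seq_len(k) - 1L,
                 function(t) A[(t * batch + 1L):((w_out + t) * batch), ,
                               drop = FALSE])
  do.call(cbind, cols)
}

nn_forward <- function(layers, X, batch, training = FALSE) {
  caches <- vector("list", length(layers))
  A <- X
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "conv2d") {
      P <- matrix(0, batch * L$w_out, nrow(L$idx))
      for (p in seq_len(L$w_out)) {
        P[((p - 1L) * batch + 1L):(p * batch), ] <- A[, L$idx[, p], drop = FALSE]
      }
      caches[[li]] <- list(P = P, in_cols = ncol(A))
      A <- addcol(P %*% L$par$W, L$par$b)
    } else if (L$type == "conv1d") {
      P <- conv1d_patches(A, L$k, batch)
      caches[[li]] <- list(P = P, in_rows = nrow(A), in_cols = ncol(A))
      A <- addcol(P %*% L$par$W, L$par$b)
    } else if (L$type == "bnorm") {
      if (training) {
        mu <- colMeans(A)
        xc <- addcol(A, -mu)
        v <- colMeans(xc * xc)
        istd <- 1 / sqrt(v + L$eps)
        xhat <- mulcol(xc, istd)
        caches[[li]] <- list(xhat = xhat, istd = istd)
        layers[[li]]$run_mean <- L$momentum * L$run_mean + (1 - L$momentum) * mu
        layers[[li]]$run_var <- L$momentum * L$run_var + (1 - L$momentum) * v
        A <- addcol(mulcol(xhat, L$par$gamma), L$par$beta)
      } else {
        xhat <- mulcol(addcol(A, -L$run_mean), 1 / sqrt(L$run_var + L$eps))
        A <- addcol(mulcol(xhat, L$par$gamma), L$par$beta)
      }
    } else if (L$type == "relu") {
      mask <- A > 0
      caches[[li]] <- list(mask = mask)
      A <- A * mask
    } else if (L$type == "dropout") {
      if (training && L$rate > 0) {
        keep <- 1 - L$rate
        mask <- matrix(runif(length(A)) < keep, nrow(A)) / keep
        caches[[li]] <- list(mask = mask)
        A <- A * mask
      }
    } else if (L$type == "flatten") {
      w <- nrow(A) / batch
      C <- ncol(A)
      out <- matrix(0, batch, w * C)
      for (p in seq_len(w)) {
        out[, ((p - 1L) * C + 1L):(p * C)] <-
          A[((p - 1L) * batch + 1L):(p * batch), , drop = FALSE]
      }
      caches[[li]] <- list(w = w, C = C)
      A <- out
    } else if (L$type == "dense") {
      caches[[li]] <- list(X = A)
      A <- addcol(A %*% L$par$W, L$par$b)
    } else if (L$type == "sigmoid") {
      A <- 1 / (1 + exp(-A))
      caches[[li]] <- list(out = A)
    }
  }
  list(out = A, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout, batch) {
  grads <- vector("list", length(layers))
  dA <- dout
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    cc <- caches[[li]]
    if (L$type == "sigmoid") {
      dA <- dA * cc$out * (1 - cc$out)
    } else if (L$type == "dense") {
      grads[[li]] <- list(W = crossprod(cc$X, dA), b = colSums(dA))
      dA <- tcrossprod(dA, L$par$W)
    } else if (L$type == "flatten") {
      prev <- matrix(0, batch * cc$w, cc$C)
      for (p in seq_len(cc$w)) {
        prev[((p - 1L) * batch + 1L):(p * batch), ] <-
          dA[, ((p - 1L) * cc$C + 1L):(p * cc$C), drop = FALSE]
      }
      dA <- prev
    } else if (L$type == "dropout") {
      if (!is.null(cc)) dA <- dA * cc$mask
    } else if (L$type == "relu") {
      dA <- dA * cc$mask
    } else if (L$type == "bnorm") {
      N <- nrow(dA)
      dgamma <- colSums(dA * cc$xhat)
      dbeta <- colSums(dA)
      grads[[li]] <- list(gamma = dgamma, beta = dbeta)
      t1 <- addcol(dA, -dbeta / N)
      t2 <- mulcol(cc$xhat, dgamma / N)
      dA <- mulcol(t1 - t2, L$par$gamma * cc$istd)
    } else if (L$type == "conv1d") {
      grads[[li]] <- list(W = crossprod(cc$P, dA), b = colSums(dA))
      dP <- tcrossprod(dA, L$par$W)
      prev <- matrix(0, cc$in_rows, cc$in_cols)
      w_out <- nrow(dA) / batch
      for (t in seq_len(L$k) - 1L) {
        rows <- (t * batch + 1L):((w_out + t) * batch)
        cols <- (t * cc$in_cols + 1L):((t + 1L) * cc$in_cols)
        prev[rows, ] <- prev[rows, ] + dP[, cols, drop = FALSE]
      }
      dA <- prev
    } else if (L$type == "conv2d") {
      grads[[li]] <- list(W = crossprod(cc$P, dA), b = colSums(dA))
      dP <- tcrossprod(dA, L$par$W)
      prev <- matrix(0, batch, cc$in_cols)
      for (p in seq_len(L$w_out)) {
        rows <- ((p - 1L) * batch + 1L):(p * batch)
        prev[, L$idx[, p]] <- prev[, L$idx[, p], drop = FALSE] +
          dP[rows, , drop = FALSE]
      }
      dA <- prev
    }
  }
  list(grads = grads, dX = dA)
}

# global-norm gradient clipping: rescales the whole gradient when its
# Euclidean norm exceeds max_norm, guarding the occasional unstable step
clip_grads <- function(grads, max_norm) {
  ss <- 0
  for (g in grads) for (p in g) ss <- ss + sum(p * p)
  nrm <- sqrt(ss)
  if (is.finite(nrm) && nrm <= max_norm) return(grads)
  scale <- max_norm / (nrm + 1e-12)
  lapply(grads, function(g) lapply(g, function(p) p * scale))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(L) {
    lapply(L$par, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      st <- state[[li]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[li]]$par[[pn]] <- layers[[li]]$par[[pn]] - lr * mh / (sqrt(vh) + eps)
      state[[li]][[pn]] <- st
    }
  }
  list(layers = layers, state = state)
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(L) sum(vapply(L$par, length, 1L)), 1))
}

# Recompute batch-normalisation running statistics for a (weight-averaged)
# layer stack: one forward pass over the data, averaging batch moments.
bn_refresh <- function(layers, X, batch_size) {
  sums <- list(); sqs <- list(); counts <- 0L
  n <- nrow(X)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    A <- X[idx, , drop = FALSE]
    batch <- length(idx)
    for (li in seq_along(layers)) {
      L <- layers[[li]]
      fw <- nn_forward(layers[li], A, batch, training = FALSE)
      if (L$type == "bnorm") {
        mu <- colMeans(A)
        xc <- addcol(A, -mu)
        v <- colMeans(xc * xc)
        key <- as.character(li)
        if (is.null(sums[[key]])) { sums[[key]] <- mu; sqs[[key]] <- v }
        else { sums[[key]] <- sums[[key]] + mu; sqs[[key]] <- sqs[[key]] + v }
        # normalise with the batch's own moments, as in training
        A <- addcol(mulcol(mulcol(xc, 1 / sqrt(v + L$eps)), L$par$gamma),
                    L$par$beta)
      } else {
        A <- fw$out
      }
    }
    counts <- counts + 1L
  }
  for (key in names(sums)) {
    li <- as.integer(key)
    layers[[li]]$run_mean <- sums[[key]] / counts
    layers[[li]]$run_var <- sqs[[key]] / counts
  }
  layers
}
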