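# Bidirectional LSTM engine for the token-encoded sequence-pair regressor.
# Gates are ordered (i, f, g, o); padding positions carry the previous
# hidden/cell state through unchanged so right-padded batches are exact.
# The readout is the last layer's hidden state at the first position (the
# begin token): the backward direction has consumed the entire pair there.

lstm_dir_init <- function(emb_dim, hidden) {
  list(Wx = glorot(emb_dim, 4L * hidden),
       Wh = glorot(hidden, 4L * hidden),
       b = numeric(4L * hidden))
}

sigm <- function(x) 1 / (1 + exp(-x))

# One direction over the embedded batch. X: list of per-step (batch x emb)
# inputs in PROCESSING order; mask: (batch x T) in processing order.
lstm_dir_forward <- function(par, X, mask, hidden) {
  Tlen <- length(X)
  batch <- nrow(X[[1]])
  h <- matrix(0, batch, hidden)
  cst <- matrix(0, batch, hidden)
  caches <- vector("list", Tlen)
  hs <- vector("list", Tlen)
  for (t in seq_len(Tlen)) {
    G <- addcol(X[[t]] %*% par$Wx + h %*% par$Wh, par$b)
    H <- hidden
    ig <- sigm(G[, 1:H, drop = FALSE])
    fg <- sigm(G[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    og <- sigm(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- fg * cst + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    m <- mask[, t]
    caches[[t]] <- list(ig = ig, fg = fg, gg = gg, og = og,
                        c_prev = cst, h_prev = h, c_new = c_new, tc = tc,
                        m = m)
    h <- h_new * m + h * (1 - m)
    cst <- c_new * m + cst * (1 - m)
    hs[[t]] <- h
  }
  list(hs = hs, caches = caches)
}

# BPTT for one direction. dh_steps: list of per-step gradients w.r.t. the
# POST-mask hidden state (zeros where no readout). Returns parameter grads
# and per-step gradients w.r.t. the inputs X[[t]].
lstm_dir_backward <- function(par, X, caches, dh_steps, hidden) {
  Tlen <- length(X)
  batch <- nrow(X[[1]])
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dXs <- vector("list", Tlen)
  dh <- matrix(0, batch, hidden)
  dc <- matrix(0, batch, hidden)
  for (t in rev(seq_len(Tlen))) {
    cc <- caches[[t]]
    dh <- dh + dh_steps[[t]]
    m <- cc$m
    dh_new <- dh * m
    dc_new <- dc * m
    dh_prev_carry <- dh * (1 - m)
    dc_prev_carry <- dc * (1 - m)
    dog <- dh_new * cc$tc
    dc_new <- dc_new + dh_new * cc$og * (1 - cc$tc^2)
    dfg <- dc_new * cc$c_prev
    dig <- dc_new * cc$gg
    dgg <- dc_new * cc$ig
    dc_prev <- dc_new * cc$fg
    dG <- cbind(dig * cc$ig * (1 - cc$ig),
                dfg * cc$fg * (1 - cc$fg),
                dgg * (1 - cc$gg^2),
                dog * cc$og * (1 - cc$og))
    dWx <- dWx + crossprod(X[[t]], dG)
    dWh <- dWh + crossprod(cc$h_prev, dG)
    db <- db + colSums(dG)
    dXs[[t]] <- tcrossprod(dG, par$Wx)
    dh <- tcrossprod(dG, par$Wh) + dh_prev_carry
    dc <- dc_prev + dc_prev_carry
  }
  list(Wx = dWx, Wh = dWh, b = db, dXs = dXs)
}
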