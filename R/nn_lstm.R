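# Recurrent (LSTM) encoder-decoder with teacher forcing.
#
# The encoder reads the source character sequence and summarizes it into
# two state vectors (hidden and cell state, each of width latent_dim).
# The decoder is initialized with those states and trained to transform
# the target sequence into the same sequence offset by one timestep
# (teacher forcing); at inference it decodes greedily, feeding back its
# own arg-max character until the end symbol.
#
# Parameters (flat named list):
#   Es, Et        source/target character embeddings (V x D)
#   enc_W, enc_U, enc_b   encoder LSTM (gate order i, f, g, o)
#   dec_W, dec_U, dec_b   decoder LSTM
#   Wo, bo        output projection (H x Vt)

lstm_init_params <- function(vs, vt, d, h) {
  p <- list(
    Es = glorot_uniform(vs, d),
    Et = glorot_uniform(vt, d),
    enc_W = glorot_uniform(d, 4 * h),
    enc_U = glorot_uniform(h, 4 * h),
    enc_b = numeric(4 * h),
    dec_W = glorot_uniform(d, 4 * h),
    dec_U = glorot_uniform(h, 4 * h),
    dec_b = numeric(4 * h),
    Wo = glorot_uniform(h, vt),
    bo = numeric(vt))
  # forget-gate bias starts open so early training retains state
  p$enc_b[(h + 1):(2 * h)] <- 1
  p$dec_b[(h + 1):(2 * h)] <- 1
  p
}

# one LSTM step; m is a 0/1 update-mask vector (pad steps keep state)
lstm_step <- function(x, h_prev, c_prev, W, U, b, m) {
  hdim <- nrow(U)
  z <- x %*% W + h_prev %*% U
  z <- sweep(z, 2L, b, "+")
  i <- sigmoid(z[, 1:hdim, drop = FALSE])
  f <- sigmoid(z[, (hdim + 1):(2 * hdim), drop = FALSE])
  g <- tanh(z[, (2 * hdim + 1):(3 * hdim), drop = FALSE])
  o <- sigmoid(z[, (3 * hdim + 1):(4 * hdim), drop = FALSE])
  c_new <- f * c_prev + i * g
  th <- tanh(c_new)
  h_new <- o * th
  h <- h_new * m + h_prev * (1 - m)
  c <- c_new * m + c_prev * (1 - m)
  list(h = h, c = c,
       cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, c_new = c_new, th = th,
                    m = m))
}

lstm_step_backward <- function(dh, dc, cache, W, U) {
  m <- cache$m
  dh_t <- dh * m
  dh_pass <- dh * (1 - m)
  dc_t <- dc * m
  dc_pass <- dc * (1 - m)
  do_ <- dh_t * cache$th
  dth <- dh_t * cache$o
  dc_t <- dc_t + dth * (1 - cache$th^2)
  di <- dc_t * cache$g
  dg <- dc_t * cache$i
  df <- dc_t * cache$c_prev
  dc_prev <- dc_t * cache$f + dc_pass
  dz <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do_ * cache$o * (1 - cache$o))
  list(dx = dz %*% t(W),
       dh_prev = dz %*% t(U) + dh_pass,
       dc_prev = dc_prev,
       dW = crossprod(cache$x, dz),
       dU = crossprod(cache$h_prev, dz),
       db = colSums(dz))
}

# run one LSTM over an index matrix; returns per-step hidden states and
# caches needed for backprop
lstm_run <- function(X_idx, E, W, U, b, pad_idx, h0, c0) {
  B <- nrow(X_idx)
  T_ <- ncol(X_idx)
  h <- h0
  c <- c0
  hs <- vector("list", T_)
  caches <- vector("list", T_)
  for (t in seq_len(T_)) {
    idx <- X_idx[, t]
    x <- E[idx, , drop = FALSE]
    m <- as.numeric(idx != pad_idx)
    st <- lstm_step(x, h, c, W, U, b, m)
    h <- st$h
    c <- st$c
    hs[[t]] <- h
    caches[[t]] <- st$cache
  }
  list(hs = hs, h = h, c = c, caches = caches)
}

# backprop through a full LSTM run; dhs: per-step gradients (NULL for
# none), dh_T/dc_T: gradient flowing into the final state
lstm_run_backward <- function(X_idx, E, W, U, caches, dhs, dh_T, dc_T) {
  B <- nrow(X_idx)
  T_ <- ncol(X_idx)
  hdim <- nrow(U)
  dW <- matrix(0, nrow(W), ncol(W))
  dU <- matrix(0, hdim, 4 * hdim)
  db <- numeric(4 * hdim)
  dh <- dh_T
  dc <- dc_T
  dx_all <- vector("list", T_)
  for (t in rev(seq_len(T_))) {
    if (!is.null(dhs)) dh <- dh + dhs[[t]]
    bk <- lstm_step_backward(dh, dc, caches[[t]], W, U)
    dW <- dW + bk$dW
    dU <- dU + bk$dU
    db <- db + bk$db
    dx_all[[t]] <- bk$dx
    dh <- bk$dh_prev
    dc <- bk$dc_prev
  }
  dE <- embedding_grad(nrow(E), as.vector(X_idx),
                       do.call(rbind, dx_all))
  list(dW = dW, dU = dU, db = db, dE = dE, dh0 = dh, dc0 = dc)
}

# full teacher-forced forward/backward pass; returns loss, accuracy and
# gradients for every parameter
lstm_loss_and_grads <- function(params, batch, vocab, hdim,
                                compute_grads = TRUE) {
  enc_in <- batch$encoder_input
  dec_in <- batch$decoder_input
  dec_tgt <- batch$decoder_target
  B <- nrow(enc_in)
  sp_s <- vocab_special(vocab, "source")
  sp_t <- vocab_special(vocab, "target")
  h0 <- matrix(0, B, hdim)
  enc <- lstm_run(enc_in, params$Es, params$enc_W, params$enc_U,
                  params$enc_b, sp_s$pad, h0, h0)
  dec <- lstm_run(dec_in, params$Et, params$dec_W, params$dec_U,
                  params$dec_b, sp_t$pad, enc$h, enc$c)
  Tu <- ncol(dec_in)
  Hdec <- do.call(rbind, dec$hs)              # (B*Tu) x H, time-major
  logits <- sweep(Hdec %*% params$Wo, 2L, params$bo, "+")
  targets <- as.vector(dec_tgt)               # time-major via column order
  mask <- as.numeric(targets != sp_t$pad)
  sm <- softmax_xent(logits, targets, mask)
  if (!compute_grads) {
    return(list(loss = sm$loss, accuracy = sm$accuracy))
  }
  dHdec <- sm$dlogits %*% t(params$Wo)
  dhs <- lapply(seq_len(Tu), function(t) {
    dHdec[((t - 1) * B + 1):(t * B), , drop = FALSE]
  })
  zero <- matrix(0, B, hdim)
  dec_bk <- lstm_run_backward(dec_in, params$Et, params$dec_W,
                              params$dec_U, dec$caches, dhs, zero, zero)
  enc_bk <- lstm_run_backward(enc_in, params$Es, params$enc_W,
                              params$enc_U, enc$caches, NULL,
                              dec_bk$dh0, dec_bk$dc0)
  grads <- list(
    Es = enc_bk$dE, Et = dec_bk$dE,
    enc_W = enc_bk$dW, enc_U = enc_bk$dU, enc_b = enc_bk$db,
    dec_W = dec_bk$dW, dec_U = dec_bk$dU, dec_b = dec_bk$db,
    Wo = crossprod(Hdec, sm$dlogits), bo = colSums(sm$dlogits))
  list(loss = sm$loss, accuracy = sm$accuracy, grads = grads)
}

# batched greedy decoding: feed back the arg-max character until the end
# symbol or the step bound
lstm_greedy_decode <- function(params, enc_in, vocab, hdim,
                               max_output_len) {
  B <- nrow(enc_in)
  sp_s <- vocab_special(vocab, "source")
  sp_t <- vocab_special(vocab, "target")
  h0 <- matrix(0, B, hdim)
  enc <- lstm_run(enc_in, params$Es, params$enc_W, params$enc_U,
                  params$enc_b, sp_s$pad, h0, h0)
  h <- enc$h
  c <- enc$c
  y <- rep(sp_t$sos, B)
  done <- rep(FALSE, B)
  out <- matrix(sp_t$pad, B, max_output_len)
  ones <- rep(1, B)
  for (t in seq_len(max_output_len)) {
    x <- params$Et[y, , drop = FALSE]
    st <- lstm_step(x, h, c, params$dec_W, params$dec_U, params$dec_b,
                    ones)
    h <- st$h
    c <- st$c
    logits <- sweep(h %*% params$Wo, 2L, params$bo, "+")
    y <- max.col(logits, ties.method = "first")
    y[done] <- sp_t$pad
    out[, t] <- y
    done <- done | y == sp_t$eos
    if (all(done)) break
    y[y == sp_t$pad] <- sp_t$eos  # keep finished rows on a valid index
  }
  out
}
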