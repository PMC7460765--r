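# Convolutional encoder-decoder with attention.
#
# The encoder embeds the source characters and applies three
# one-dimensional convolution layers (kernel 3, same padding).  The
# target side embeds the offset target sequence and applies three causal
# one-dimensional convolution layers, so position t sees only positions
# <= t and training matches step-by-step inference.  A scaled dot-product
# attention layer lets every decoder position attend over the encoder
# outputs (source pad positions masked out); decoder stream and context
# are concatenated and decoded by two further causal convolution layers
# and a per-step softmax over target characters.
#
# Parameters (flat named list): Es, Et; enc1..enc3, dec1..dec3,
# out1..out2 as {prefix}_W1..W3 + {prefix}_b; Wo, bo.

CNN_KERNEL <- 3L

cnn_layer_names <- function() {
  c(paste0("enc", 1:3), paste0("dec", 1:3), paste0("out", 1:2))
}

cnn_init_params <- function(vs, vt, d, h) {
  p <- list(Es = glorot_uniform(vs, d), Et = glorot_uniform(vt, d))
  dims <- list(enc1 = c(d, h), enc2 = c(h, h), enc3 = c(h, h),
               dec1 = c(d, h), dec2 = c(h, h), dec3 = c(h, h),
               out1 = c(2 * h, h), out2 = c(h, h))
  for (nm in names(dims)) {
    cl <- conv_init(CNN_KERNEL, dims[[nm]][1], dims[[nm]][2])
    for (j in seq_len(CNN_KERNEL)) p[[paste0(nm, "_W", j)]] <- cl$W[[j]]
    p[[paste0(nm, "_b")]] <- cl$b
  }
  p$Wo <- glorot_uniform(h, vt)
  p$bo <- numeric(vt)
  p
}

layer_view <- function(params, prefix) {
  list(W = lapply(seq_len(CNN_KERNEL),
                  function(j) params[[paste0(prefix, "_W", j)]]),
       b = params[[paste0(prefix, "_b")]])
}

# conv + relu stack; returns activations of every layer for backprop
cnn_stack_forward <- function(params, prefixes, x, B, T, causal) {
  acts <- vector("list", length(prefixes) + 1L)
  acts[[1]] <- x
  for (l in seq_along(prefixes)) {
    z <- conv_forward(acts[[l]], layer_view(params, prefixes[l]), B, T,
                      causal)
    acts[[l + 1L]] <- relu(z)
  }
  acts
}

cnn_stack_backward <- function(params, prefixes, acts, dtop, B, T,
                               causal, grads) {
  dy <- dtop
  for (l in rev(seq_along(prefixes))) {
    dy <- dy * (acts[[l + 1L]] > 0)          # relu gate
    bk <- conv_backward(dy, acts[[l]], layer_view(params, prefixes[l]),
                        B, T, causal)
    for (j in seq_len(CNN_KERNEL)) {
      nm <- paste0(prefixes[l], "_W", j)
      grads[[nm]] <- grads[[nm]] + bk$dW[[j]]
    }
    nb <- paste0(prefixes[l], "_b")
    grads[[nb]] <- grads[[nb]] + bk$db
    dy <- bk$dx
  }
  list(dx = dy, grads = grads)
}

# scaled dot-product attention of decoder states over encoder states.
# dec: (B*Tu) x H, enc: (B*Ts) x H, src_mask: B x Ts (1 = real char).
cnn_attention_forward <- function(dec, enc, src_mask, B, Tu, Ts, hdim) {
  ctx <- matrix(0, nrow(dec), hdim)
  A <- vector("list", B)
  scale <- 1 / sqrt(hdim)
  for (b in seq_len(B)) {
    rows_u <- seq(b, by = B, length.out = Tu)
    rows_s <- seq(b, by = B, length.out = Ts)
    S <- (dec[rows_u, , drop = FALSE] %*%
            t(enc[rows_s, , drop = FALSE])) * scale
    S[, src_mask[b, ] == 0] <- -1e30
    Ab <- row_softmax(S)
    A[[b]] <- Ab
    ctx[rows_u, ] <- Ab %*% enc[rows_s, , drop = FALSE]
  }
  list(ctx = ctx, A = A)
}

cnn_attention_backward <- function(dctx, dec, enc, A, B, Tu, Ts, hdim) {
  ddec <- matrix(0, nrow(dec), hdim)
  denc <- matrix(0, nrow(enc), hdim)
  scale <- 1 / sqrt(hdim)
  for (b in seq_len(B)) {
    rows_u <- seq(b, by = B, length.out = Tu)
    rows_s <- seq(b, by = B, length.out = Ts)
    Ab <- A[[b]]
    dctx_b <- dctx[rows_u, , drop = FALSE]
    enc_b <- enc[rows_s, , drop = FALSE]
    dA <- dctx_b %*% t(enc_b)
    denc[rows_s, ] <- denc[rows_s, ] + t(Ab) %*% dctx_b
    dS <- Ab * (dA - rowSums(dA * Ab))
    ddec[rows_u, ] <- ddec[rows_u, ] +
      (dS %*% enc_b) * scale
    denc[rows_s, ] <- denc[rows_s, ] +
      t(dS) %*% dec[rows_u, , drop = FALSE] * scale
  }
  list(ddec = ddec, denc = denc)
}

cnn_forward <- function(params, enc_in, dec_in, vocab, hdim) {
  B <- nrow(enc_in)
  Ts <- ncol(enc_in)
  Tu <- ncol(dec_in)
  sp_s <- vocab_special(vocab, "source")
  src_mask <- matrix(as.numeric(enc_in != sp_s$pad), B, Ts)
  xs <- params$Es[as.vector(enc_in), , drop = FALSE]   # time-major
  xt <- params$Et[as.vector(dec_in), , drop = FALSE]
  enc_acts <- cnn_stack_forward(params, paste0("enc", 1:3), xs, B, Ts,
                                causal = FALSE)
  dec_acts <- cnn_stack_forward(params, paste0("dec", 1:3), xt, B, Tu,
                                causal = TRUE)
  enc_top <- enc_acts[[4]]
  dec_top <- dec_acts[[4]]
  att <- cnn_attention_forward(dec_top, enc_top, src_mask, B, Tu, Ts,
                               hdim)
  comb <- cbind(dec_top, att$ctx)
  out_acts <- cnn_stack_forward(params, paste0("out", 1:2), comb, B, Tu,
                                causal = TRUE)
  logits <- sweep(out_acts[[3]] %*% params$Wo, 2L, params$bo, "+")
  list(logits = logits, enc_acts = enc_acts, dec_acts = dec_acts,
       att = att, comb = comb, out_acts = out_acts,
       src_mask = src_mask, B = B, Ts = Ts, Tu = Tu)
}

cnn_loss_and_grads <- function(params, batch, vocab, hdim,
                               compute_grads = TRUE) {
  fw <- cnn_forward(params, batch$encoder_input, batch$decoder_input,
                    vocab, hdim)
  sp_t <- vocab_special(vocab, "target")
  targets <- as.vector(batch$decoder_target)
  mask <- as.numeric(targets != sp_t$pad)
  sm <- softmax_xent(fw$logits, targets, mask)
  if (!compute_grads) {
    return(list(loss = sm$loss, accuracy = sm$accuracy))
  }
  B <- fw$B
  Ts <- fw$Ts
  Tu <- fw$Tu
  grads <- lapply(params, function(p) p * 0)
  grads$Wo <- crossprod(fw$out_acts[[3]], sm$dlogits)
  grads$bo <- colSums(sm$dlogits)
  dtop <- sm$dlogits %*% t(params$Wo)
  outb <- cnn_stack_backward(params, paste0("out", 1:2), fw$out_acts,
                             dtop, B, Tu, causal = TRUE, grads)
  grads <- outb$grads
  dcomb <- outb$dx
  ddec_top <- dcomb[, seq_len(hdim), drop = FALSE]
  dctx <- dcomb[, hdim + seq_len(hdim), drop = FALSE]
  attb <- cnn_attention_backward(dctx, fw$dec_acts[[4]], fw$enc_acts[[4]],
                                 fw$att$A, B, Tu, Ts, hdim)
  ddec_top <- ddec_top + attb$ddec
  decb <- cnn_stack_backward(params, paste0("dec", 1:3), fw$dec_acts,
                             ddec_top, B, Tu, causal = TRUE, grads)
  grads <- decb$grads
  encb <- cnn_stack_backward(params, paste0("enc", 1:3), fw$enc_acts,
                             attb$denc, B, Ts, causal = FALSE, grads)
  grads <- encb$grads
  grads$Et <- embedding_grad(nrow(params$Et),
                             as.vector(batch$decoder_input), decb$dx)
  grads$Es <- embedding_grad(nrow(params$Es),
                             as.vector(batch$encoder_input), encb$dx)
  list(loss = sm$loss, accuracy = sm$accuracy, grads = grads)
}

# greedy decoding by re-running the causal target stack over the growing
# prefix and reading the distribution at the last position
cnn_greedy_decode <- function(params, enc_in, vocab, hdim,
                              max_output_len) {
  B <- nrow(enc_in)
  Ts <- ncol(enc_in)
  sp_s <- vocab_special(vocab, "source")
  sp_t <- vocab_special(vocab, "target")
  src_mask <- matrix(as.numeric(enc_in != sp_s$pad), B, Ts)
  xs <- params$Es[as.vector(enc_in), , drop = FALSE]
  enc_top <- cnn_stack_forward(params, paste0("enc", 1:3), xs, B, Ts,
                               causal = FALSE)[[4]]
  prefix <- matrix(sp_t$sos, B, 1L)
  done <- rep(FALSE, B)
  out <- matrix(sp_t$pad, B, max_output_len)
  for (t in seq_len(max_output_len)) {
    Tu <- ncol(prefix)
    xt <- params$Et[as.vector(prefix), , drop = FALSE]
    dec_top <- cnn_stack_forward(params, paste0("dec", 1:3), xt, B, Tu,
                                 causal = TRUE)[[4]]
    att <- cnn_attention_forward(dec_top, enc_top, src_mask, B, Tu, Ts,
                                 hdim)
    comb <- cbind(dec_top, att$ctx)
    out_top <- cnn_stack_forward(params, paste0("out", 1:2), comb, B, Tu,
                                 causal = TRUE)[[3]]
    last_rows <- ((Tu - 1L) * B + 1L):(Tu * B)
    logits <- sweep(out_top[last_rows, , drop = FALSE] %*% params$Wo,
                    2L, params$bo, "+")
    y <- max.col(logits, ties.method = "first")
    y[done] <- sp_t$pad
    out[, t] <- y
    done <- done | y == sp_t$eos
    if (all(done)) break
    y_feed <- y
    y_feed[y_feed == sp_t$pad] <- sp_t$eos
    prefix <- cbind(prefix, y_feed)
  }
  out
}
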