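# Shared numerical machinery for the neural translators: parameter
# initialization, the Adam optimizer, masked softmax cross-entropy, and
# time-shift/convolution primitives used by the convolutional model.
#
# Sequence activations are stored time-major: a (B*T) x C matrix whose
# rows (t-1)*B + 1 .. t*B hold timestep t for the whole minibatch, so a
# temporal shift is a contiguous block copy and a 1-d convolution is a
# sum of shifted matrix products.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# numerically stable row-wise softmax
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# masked cross-entropy over flattened logits; targets is an integer
# vector (one class per row), mask a 0/1 vector.  Returns loss per
# non-masked token, the probability matrix and dlogits (already divided
# by the token count) for backpropagation.
softmax_xent <- function(logits, targets, mask) {
  p <- row_softmax(logits)
  n_tok <- sum(mask)
  idx <- cbind(seq_along(targets), targets)
  eps <- 1e-12
  loss <- -sum(log(p[idx] + eps) * mask) / max(n_tok, 1)
  acc <- sum((max.col(p, ties.method = "first") == targets) * mask) /
    max(n_tok, 1)
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (mask / max(n_tok, 1))
  list(loss = loss, accuracy = acc, dlogits = dlogits)
}

# global-norm gradient clipping
clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}

# Adam optimizer state held in an environment keyed by parameter name
adam_state <- function() {
  new.env(parent = emptyenv())
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- if (is.null(state$t)) 1L else state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state[[paste0("m_", nm)]]
    v <- state[[paste0("v_", nm)]]
    if (is.null(m)) {
      m <- g * 0
      v <- g * 0
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state[[paste0("m_", nm)]] <- m
    state[[paste0("v_", nm)]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}

# accumulate rows of `grad_rows` into an embedding gradient by index
embedding_grad <- function(n_rows, idx, grad_rows) {
  out <- matrix(0, n_rows, ncol(grad_rows))
  agg <- rowsum(grad_rows, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# time-major block shift: result row-block t equals input block t + off
# (zero where t + off falls outside 1..T)
shift_time <- function(x, off, B, T) {
  res <- matrix(0, nrow(x), ncol(x))
  t1 <- max(1L, 1L - off)
  t2 <- min(T, T - off)
  if (t1 > t2) return(res)
  dest <- ((t1 - 1L) * B + 1L):(t2 * B)
  src <- ((t1 + off - 1L) * B + 1L):((t2 + off) * B)
  res[dest, ] <- x[src, , drop = FALSE]
  res
}

conv_offsets <- function(k, causal) {
  if (causal) -(k - 1L):0L else -((k - 1L) %/% 2L):((k - 1L) %/% 2L)
}

conv_init <- function(k, c_in, c_out) {
  list(W = lapply(seq_len(k), function(j) glorot_uniform(c_in, c_out)),
       b = numeric(c_out))
}

# 1-d convolution along time; x is (B*T) x Cin time-major
conv_forward <- function(x, layer, B, T, causal) {
  k <- length(layer$W)
  off <- conv_offsets(k, causal)
  y <- matrix(layer$b, nrow(x), length(layer$b), byrow = TRUE)
  for (j in seq_len(k)) {
    y <- y + shift_time(x, off[j], B, T) %*% layer$W[[j]]
  }
  y
}

conv_backward <- function(dy, x, layer, B, T, causal) {
  k <- length(layer$W)
  off <- conv_offsets(k, causal)
  dW <- vector("list", k)
  dx <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) {
    dW[[j]] <- crossprod(shift_time(x, off[j], B, T), dy)
    dx <- dx + shift_time(dy %*% t(layer$W[[j]]), -off[j], B, T)
  }
  list(dW = dW, db = colSums(dy), dx = dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
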