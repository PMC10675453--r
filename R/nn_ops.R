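# Low-level neural-network operations.
#
# Batched sequence tensors are represented throughout as flat (B*T, C)
# matrices in the column-major order of a (batch, time, channels) array:
# row index = b + (t-1)*B. In this layout a temporal shift is a contiguous
# row-block shift of B rows, channel concatenation is cbind, and time
# reversal is a row permutation — all cheap. The batch size B and sequence
# length T are carried alongside by the caller (the model knows the shape
# at every level). Every operation has a forward returning list(out, cache)
# and a backward returning input/parameter gradients; all gradients are
# validated against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise bias add without sweep()'s aperm overhead
add_bias <- function(Y, b) Y + rep(b, each = nrow(Y))

# rows of time step t
t_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# row permutation that reverses time
rev_rows <- function(B, Tn) rep((Tn:1 - 1L) * B, each = B) + seq_len(B)

# ---- 1-D convolution, 'same' zero padding ---------------------------------

# W is a (k*Cin) x Cout matrix (tap-major, channel within tap), b length
# Cout. The tap-shift accumulation runs compiled (src/lstm.cpp).
conv1d_forward <- function(Xm, B, Tn, W, b, k) {
  list(out = conv1d_forward_cpp(Xm, W, b, k, B, Tn),
       cache = list(Xm = Xm, W = W, k = k, B = B, Tn = Tn))
}

conv1d_backward <- function(dY, cache) {
  bk <- conv1d_backward_cpp(dY, cache$Xm, cache$W, cache$k, cache$B,
                            cache$Tn)
  list(dX = bk$dX, dW = bk$dW, db = as.numeric(bk$db))
}

# ---- ReLU -----------------------------------------------------------------

relu_forward <- function(X) {
  list(out = pmax(X, 0), cache = X > 0)
}

relu_backward <- function(dY, cache) dY * cache

# ---- Max pooling / nearest upsampling, factor 2 ---------------------------

pool_rows <- function(B, Tn) {
  list(odd = rep((seq.int(1L, Tn, 2L) - 1L) * B, each = B) + seq_len(B),
       even = rep((seq.int(2L, Tn, 2L) - 1L) * B, each = B) + seq_len(B))
}

maxpool2_forward <- function(Xm, B, Tn) {
  stopifnot(Tn %% 2L == 0L)
  pr <- pool_rows(B, Tn)
  x1 <- Xm[pr$odd, , drop = FALSE]
  x2 <- Xm[pr$even, , drop = FALSE]
  m <- x1 >= x2
  list(out = pmax(x1, x2), cache = list(m = m, pr = pr, n_in = B * Tn))
}

maxpool2_backward <- function(dY, cache) {
  dX <- matrix(0, cache$n_in, ncol(dY))
  dX[cache$pr$odd, ] <- dY * cache$m
  dX[cache$pr$even, ] <- dY * (1 - cache$m)
  dX
}

upsample2_forward <- function(Xm, B, Tn) {
  pr <- pool_rows(B, 2L * Tn)
  Y <- matrix(0, 2L * B * Tn, ncol(Xm))
  Y[pr$odd, ] <- Xm
  Y[pr$even, ] <- Xm
  list(out = Y, cache = pr)
}

upsample2_backward <- function(dY, pr) {
  dY[pr$odd, , drop = FALSE] + dY[pr$even, , drop = FALSE]
}

# ---- LSTM (single direction) ----------------------------------------------

# Gate layout in the 4u columns: input, forget, cell, output. The input
# projection X.Wx + b is hoisted out of the time loop as one matrix
# product; the sequential recurrence runs compiled (src/lstm.cpp).
lstm_forward <- function(Xm, B, Tn, p) {
  XW <- add_bias(Xm %*% p$Wx, p$b)
  st <- lstm_forward_cpp(XW, p$Wh, B, Tn)
  list(out = st$H,
       cache = list(Xm = Xm, Ig = st$Ig, Fg = st$Fg, Gg = st$Gg, Og = st$Og,
                    Cs = st$Cs, TC = st$TC, H = st$H, p = p,
                    u = nrow(p$Wh), B = B, Tn = Tn))
}

# dH_seq: gradient w.r.t. every hidden state (may be NULL for none);
# dh_last: extra gradient on the final state (final-state mode).
lstm_backward <- function(dH_seq, dh_last, cache) {
  p <- cache$p
  bk <- lstm_backward_cpp(
    if (is.null(dH_seq)) matrix(0, 0, cache$u) else dH_seq,
    dh_last, p$Wh, cache$Ig, cache$Fg, cache$Gg, cache$Og, cache$Cs,
    cache$TC, cache$H, cache$B, cache$Tn
  )
  list(dX = tcrossprod(bk$dA, p$Wx),
       grads = list(Wx = crossprod(cache$Xm, bk$dA),
                    Wh = bk$dWh, b = colSums(bk$dA)))
}

# Bidirectional LSTM. mode = "seq" returns the (B*T, 2u) concatenated
# hidden sequence; mode = "final" returns the (B, 2u) concatenation of each
# direction's final state.
bilstm_forward <- function(Xm, B, Tn, p, mode = c("seq", "final")) {
  mode <- match.arg(mode)
  rr <- rev_rows(B, Tn)
  fwd <- lstm_forward(Xm, B, Tn, p$f)
  bwd <- lstm_forward(Xm[rr, , drop = FALSE], B, Tn, p$b)
  if (mode == "seq") {
    out <- cbind(fwd$out, bwd$out[rr, , drop = FALSE])
  } else {
    last <- t_rows(Tn, B)
    out <- cbind(fwd$out[last, , drop = FALSE],
                 bwd$out[last, , drop = FALSE])
  }
  list(out = out, cache = list(f = fwd$cache, b = bwd$cache, mode = mode,
                               u = nrow(p$f$Wh), B = B, Tn = Tn, rr = rr))
}

bilstm_backward <- function(dout, cache) {
  u <- cache$u
  B <- cache$B; Tn <- cache$Tn
  rr <- cache$rr
  zero_h <- matrix(0, B, u)
  if (cache$mode == "seq") {
    dF <- dout[, 1:u, drop = FALSE]
    dB <- dout[rr, u + 1:u, drop = FALSE]
    bf <- lstm_backward(dF, zero_h, cache$f)
    bb <- lstm_backward(dB, zero_h, cache$b)
  } else {
    bf <- lstm_backward(NULL, dout[, 1:u, drop = FALSE], cache$f)
    bb <- lstm_backward(NULL, dout[, u + 1:u, drop = FALSE], cache$b)
  }
  list(dX = bf$dX + bb$dX[rr, , drop = FALSE],
       grads = list(f = bf$grads, b = bb$grads))
}

# ---- Dense ----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = add_bias(X %*% W, b), cache = list(X = X, W = W))
}

dense_backward <- function(dY, cache) {
  list(dX = tcrossprod(dY, cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# ---- Parameter tree utilities ---------------------------------------------

# Apply f elementwise across parallel nested lists of numeric arrays.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)

# One Adam update; returns list(params, m, v).
adam_step <- function(params, grads, m, v, lr, step,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- tree_map(function(mm, g) beta1 * mm + (1 - beta1) * g, m, grads)
  v <- tree_map(function(vv, g) beta2 * vv + (1 - beta2) * g^2, v, grads)
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  params <- tree_map(function(p, mm, vv) {
    p - lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
  }, params, m, v)
  list(params = params, m = m, v = v)
}
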