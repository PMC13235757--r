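# Primitive differentiable layers over (H, W, C, N) image/feature arrays.
# Convolutions are im2col + GEMM (C++ kernels); every layer has an explicit
# backward pass returning input and parameter gradients.

conv_layer <- function(cin, cout, k, s, p, init = c("xavier", "normal"),
                       sd = 0.01) {
  init <- match.arg(init)
  fan_in <- k * k * cin
  fan_out <- k * k * cout
  W <- if (init == "xavier") {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(cout * fan_in, -lim, lim), nrow = cout)
  } else {
    matrix(stats::rnorm(cout * fan_in, sd = sd), nrow = cout)
  }
  list(W = W, b = numeric(cout), k = k, s = s, p = p, cin = cin, cout = cout)
}

conv_out_hw <- function(h, k, s, p) (h + 2 * p - k) %/% s + 1

conv_forward <- function(layer, x, keep_cache = TRUE) {
  d <- dim(x)
  ho <- conv_out_hw(d[1], layer$k, layer$s, layer$p)
  wo <- conv_out_hw(d[2], layer$k, layer$s, layer$p)
  cols <- nl_im2col(x, d[1], d[2], d[3], d[4], layer$k, layer$s, layer$p)
  y <- layer$W %*% cols + layer$b
  dim(y) <- c(layer$cout, ho, wo, d[4])
  y <- aperm(y, c(2, 3, 1, 4))
  list(y = y, cache = if (keep_cache) list(cols = cols, xdim = d) else NULL)
}

conv_backward <- function(layer, cache, dy, need_dx = TRUE) {
  d <- dim(dy)
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(layer$cout, d[1] * d[2] * d[4])
  dW <- tcrossprod(dym, cache$cols)
  db <- rowSums(dym)
  dx <- NULL
  if (need_dx) {
    dcols <- crossprod(layer$W, dym)
    xd <- cache$xdim
    dx <- nl_col2im(dcols, xd[1], xd[2], xd[3], xd[4],
                    layer$k, layer$s, layer$p)
  }
  list(dW = dW, db = db, dx = dx)
}

relu_forward <- function(x) {
  y <- nl_relu(x)
  dim(y) <- dim(x)
  y
}

relu_backward <- function(y, dy) {
  dx <- nl_relu_backward(y, dy)
  dim(dx) <- dim(dy)
  dx
}

maxpool_forward <- function(x, k, s, p = 0L) {
  d <- dim(x)
  nl_maxpool(x, d[1], d[2], d[3], d[4], k, s, p)
}

maxpool_backward <- function(argmax, dy, xdim) {
  nl_maxpool_backward(dy, argmax, xdim[1], xdim[2], xdim[3], xdim[4])
}

# Global average pool (H, W, C, N) -> C x N, and its adjoint.
gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])
}

gap_backward <- function(dy, xdim) {
  scale <- 1 / (xdim[1] * xdim[2])
  array(rep(as.vector(dy) * scale, each = xdim[1] * xdim[2]), xdim)
}

dense_layer <- function(din, dout, init = c("xavier", "normal"), sd = 0.01) {
  init <- match.arg(init)
  W <- if (init == "xavier") {
    lim <- sqrt(6 / (din + dout))
    matrix(stats::runif(dout * din, -lim, lim), nrow = dout)
  } else {
    matrix(stats::rnorm(dout * din, sd = sd), nrow = dout)
  }
  list(W = W, b = numeric(dout))
}

# x: din x N column-major batch
dense_forward <- function(layer, x) layer$W %*% x + layer$b

dense_backward <- function(layer, x, dy) {
  list(dW = tcrossprod(dy, x), db = rowSums(dy), dx = crossprod(layer$W, dy))
}

# Flatten an (H, W, C, N) tap to one row per image; p = H*W*C.
flatten_tap <- function(x) {
  d <- dim(x)
  t(matrix(x, d[1] * d[2] * d[3], d[4]))
}

unflatten_tap <- function(g, xdim) {
  array(t(g), xdim)
}

# Softmax cross-entropy over logits (K x N) with integer labels in 1..K.
softmax_xent <- function(logits, labels, grad = FALSE) {
  K <- nrow(logits)
  N <- ncol(logits)
  mx <- apply(logits, 2L, max)
  ex <- exp(sweep(logits, 2L, mx))
  den <- colSums(ex)
  P <- sweep(ex, 2L, den, `/`)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(P[cbind(labels, seq_len(N))] + 1e-300))
  if (!grad) return(loss)
  G <- P
  G[idx] <- G[idx] - 1
  list(value = loss, dlogits = G / N)
}
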